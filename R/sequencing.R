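## Read-count simulation for pools and individual segregants

#' Specify the sequencing model
#'
#' Depth per marker follows a negative-binomial law around `mean_depth`
#' (variance `mu + dispersion * mu^2`; `dispersion = 0` gives Poisson).
#' Each read reports the sampled segregant's true allele, flipped with
#' probability `error_rate`. Mean base qualities are Gaussian around
#' `mean_phred`, truncated to the PHRED range [2, 41].
#'
#' @param mean_depth mean read depth per marker (> 0 for informative data;
#'   0 is allowed and produces uncovered markers).
#' @param dispersion negative-binomial overdispersion (>= 0).
#' @param error_rate per-base error probability in `[0, 0.5)`.
#' @param mean_phred mean reported base quality.
#' @param phred_sd standard deviation of the reported quality.
#' @return an object of class `sequencing_spec`.
#' @export
sequencing_spec <- function(mean_depth = 50, dispersion = 0.05,
                            error_rate = 0.002, mean_phred = 37,
                            phred_sd = 1.5) {
  stopifnot(mean_depth >= 0, dispersion >= 0,
            error_rate >= 0, error_rate < 0.5, phred_sd >= 0)
  structure(list(mean_depth = mean_depth, dispersion = dispersion,
                 error_rate = error_rate, mean_phred = mean_phred,
                 phred_sd = phred_sd),
            class = "sequencing_spec")
}

draw_depth <- function(n, spec) {
  if (spec$mean_depth == 0) return(integer(n))
  if (spec$dispersion == 0) {
    stats::rpois(n, spec$mean_depth)
  } else {
    stats::rnbinom(n, size = 1 / spec$dispersion, mu = spec$mean_depth)
  }
}

draw_phred <- function(n, spec) {
  pmin(41, pmax(2, stats::rnorm(n, spec$mean_phred, spec$phred_sd)))
}

#' Construct an allele-count matrix
#'
#' The central read-evidence container: per-marker counts of reads carrying
#' the superior and the inferior parent's allele, and the mean base quality,
#' for one or more samples (a pool, or each individual segregant).
#'
#' @param markers a `marker_table`.
#' @param sup,inf,qual numeric matrices, markers x samples.
#' @param samples character vector of unique sample labels.
#' @return an object of class `allele_counts` with elements `markers`,
#'   `sup`, `inf`, `qual`, `samples`.
#' @export
allele_counts <- function(markers, sup, inf, qual, samples) {
  sup <- as.matrix(sup); inf <- as.matrix(inf); qual <- as.matrix(qual)
  stopifnot(nrow(sup) == nrow(markers), identical(dim(sup), dim(inf)),
            identical(dim(sup), dim(qual)),
            length(samples) == ncol(sup), !anyDuplicated(samples))
  if (any(sup < 0, na.rm = TRUE) || any(inf < 0, na.rm = TRUE))
    stop("negative read counts")
  colnames(sup) <- colnames(inf) <- colnames(qual) <- samples
  structure(list(markers = markers, sup = sup, inf = inf, qual = qual,
                 samples = samples),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat("Allele counts:", nrow(x$markers), "markers x", length(x$samples),
      "sample(s)\n")
  cov <- x$sup + x$inf
  cat("  mean coverage:", round(mean(cov, na.rm = TRUE), 1),
      " masked cells:", sum(is.na(cov)), "\n")
  invisible(x)
}

# true allele matrix (+1/-1), markers x segregants
allele_matrix <- function(segregants, markers) {
  vapply(segregants, mosaic_alleles, integer(nrow(markers)), markers = markers)
}

#' Sequence a pooled DNA sample of selected segregants
#'
#' Pooling is equimolar: each read samples a segregant uniformly, reports its
#' allele at the marker, and is flipped with the per-base error rate.
#'
#' @param selection a [select_top()] result, or a plain list of segregants.
#' @param markers a `marker_table`.
#' @param spec a [sequencing_spec()].
#' @param seed integer seed (`NULL` = current RNG stream).
#' @param sample_name label for the pooled sample.
#' @return an [allele_counts()] with one sample column.
#' @export
sequence_pool <- function(selection, markers, spec, seed = NULL,
                          sample_name = "pool") {
  segs <- if (inherits(selection, "selection")) selection$segregants else selection
  if (length(segs) == 0L) stop("empty selection")
  if (!is.null(seed)) set.seed(stage_seed(seed, "sequencing"))
  n <- nrow(markers)
  fsup <- rowMeans(allele_matrix(segs, markers) == 1L)
  depth <- draw_depth(n, spec)
  p <- fsup * (1 - spec$error_rate) + (1 - fsup) * spec$error_rate
  sup <- stats::rbinom(n, depth, p)
  allele_counts(markers, sup, depth - sup, draw_phred(n, spec), sample_name)
}

#' Sequence selected segregants individually
#'
#' Applies the [sequence_pool()] read model to each segregant separately,
#' yielding one count column per segregant.
#'
#' @inheritParams sequence_pool
#' @param sample_names labels; defaults to `seg_1 ... seg_k` (ranked order
#'   when `selection` is a [select_top()] result).
#' @return an [allele_counts()] with one column per segregant.
#' @export
sequence_segregants <- function(selection, markers, spec, seed = NULL,
                                sample_names = NULL) {
  segs <- if (inherits(selection, "selection")) selection$segregants else selection
  if (length(segs) == 0L) stop("empty selection")
  if (!is.null(seed)) set.seed(stage_seed(seed, "sequencing"))
  k <- length(segs)
  if (is.null(sample_names)) sample_names <- sprintf("seg_%d", seq_len(k))
  n <- nrow(markers)
  A <- allele_matrix(segs, markers)
  sup <- inf <- qual <- matrix(0, n, k)
  for (j in seq_len(k)) {
    depth <- draw_depth(n, spec)
    p <- ifelse(A[, j] == 1L, 1 - spec$error_rate, spec$error_rate)
    s <- stats::rbinom(n, depth, p)
    sup[, j] <- s
    inf[, j] <- depth - s
    qual[, j] <- draw_phred(n, spec)
  }
  allele_counts(markers, sup, inf, qual, sample_names)
}
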
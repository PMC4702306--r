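## Pooled-segregant QTL mapping: variant frequency, smoothing, linkage calls

#' Mask low-quality marker observations
#'
#' A marker is masked (set `NA`) in a sample when its read coverage or its
#' mean base quality falls below threshold. Thresholds are inclusive:
#' coverage 15 at the default `min_coverage = 15` is retained. Marker
#' ordering is preserved.
#'
#' @param counts an [allele_counts()].
#' @param min_coverage minimum read coverage (default 15).
#' @param min_quality minimum mean PHRED quality (default 35).
#' @return a filtered [allele_counts()].
#' @export
quality_filter <- function(counts, min_coverage = 15, min_quality = 35) {
  stopifnot(inherits(counts, "allele_counts"),
            min_coverage >= 0, min_quality >= 0)
  cov <- counts$sup + counts$inf
  bad <- is.na(cov) | cov < min_coverage | is.na(counts$qual) |
    counts$qual < min_quality
  counts$sup[bad] <- NA_real_
  counts$inf[bad] <- NA_real_
  counts$qual[bad] <- NA_real_
  counts
}

#' SNP variant frequency of the superior parent's allele
#'
#' The variant frequency at a marker is the superior-allele read count
#' divided by the total aligned reads, a figure between 0 and 1; 0.5 is the
#' Mendelian expectation under random segregation. Markers without coverage
#' are reported `NA`.
#'
#' @param counts an [allele_counts()].
#' @param sample sample label or column index.
#' @return a `data.frame` of class `variant_freq` with columns `chrom`,
#'   `pos`, `f`, `coverage`.
#' @export
variant_frequency <- function(counts, sample = 1L) {
  stopifnot(inherits(counts, "allele_counts"))
  if (is.character(sample) && !sample %in% counts$samples)
    stop("unknown sample: ", sample)
  s <- counts$sup[, sample]
  i <- counts$inf[, sample]
  cov <- s + i
  f <- ifelse(!is.na(cov) & cov > 0, s / cov, NA_real_)
  out <- data.frame(chrom = counts$markers$chrom, pos = counts$markers$pos,
                    f = f, coverage = cov)
  class(out) <- c("variant_freq", "data.frame")
  out
}

#' Smooth a variant-frequency series along the genome
#'
#' Kernel-weighted local binomial estimation: at each covered marker the
#' superior and total read counts of neighbouring markers are combined with
#' Gaussian weights in physical distance, and the frequency estimate with a
#' normal-approximation confidence band is formed on the logit scale. The
#' band plays the role of a trend-plus-uncertainty summary against which
#' deviation from 0.5 is judged. A continuity correction of half a read
#' keeps estimates off the boundary; a chromosome with a single covered
#' marker yields that marker's frequency with its binomial error.
#'
#' When the sample is a pool of `pool_size` segregants, the pool carries at
#' most `pool_size` independent genomes at any locus, and this composition
#' noise is shared by all linked markers, so read depth alone overstates
#' precision; supplying `pool_size` caps the effective sample size
#' harmonically (`1/n_eff + 1/pool_size`), which keeps the band honest
#' against segregant-sampling drift.
#'
#' @param series a [variant_frequency()] result.
#' @param bandwidth Gaussian kernel standard deviation in base pairs
#'   (default 20000); the kernel is truncated at 4 bandwidths.
#' @param alpha band level: pointwise coverage is `1 - alpha`.
#' @param pool_size number of segregants in the pool, or `NULL` for a pure
#'   read-sampling error model.
#' @return a `data.frame` of class `smoothed_curve` with columns `chrom`,
#'   `pos`, `fit`, `lower`, `upper`, `se_logit`; attribute `bandwidth`.
#' @export
smooth_frequencies <- function(series, bandwidth = 20000, alpha = 0.05,
                               pool_size = NULL) {
  stopifnot(bandwidth > 0, alpha > 0, alpha < 1)
  keep <- !is.na(series$f) & series$coverage > 0
  dat <- series[keep, , drop = FALSE]
  if (nrow(dat) == 0L) stop("no covered markers to smooth")
  z <- stats::qnorm(1 - alpha / 2)
  parts <- lapply(split(seq_len(nrow(dat)), dat$chrom), function(idx) {
    pos <- dat$pos[idx]
    nsup <- dat$f[idx] * dat$coverage[idx]
    ntot <- dat$coverage[idx]
    W <- kernel_weights(pos, bandwidth, normalize = FALSE)
    S <- as.numeric(W %*% nsup)
    N <- as.numeric(W %*% ntot)
    neff <- N^2 / as.numeric((W^2) %*% ntot)
    if (!is.null(pool_size)) neff <- 1 / (1 / neff + 1 / pool_size)
    phat <- (S + 0.5) / (N + 1)
    se <- sqrt(1 / (neff * phat * (1 - phat)))
    lo <- stats::plogis(stats::qlogis(phat) - z * se)
    hi <- stats::plogis(stats::qlogis(phat) + z * se)
    data.frame(chrom = dat$chrom[idx], pos = pos, fit = phat,
               lower = lo, upper = hi, se_logit = se)
  })
  out <- do.call(rbind, parts)
  out <- out[order(match(out$chrom, unique(series$chrom)), out$pos), ]
  rownames(out) <- NULL
  attr(out, "bandwidth") <- bandwidth
  attr(out, "alpha") <- alpha
  class(out) <- c("smoothed_curve", "data.frame")
  out
}

# banded row-normalised Gaussian weight matrix over sorted positions,
# truncated at 4 standard deviations; sparse so that one matrix serves
# whole count matrices
kernel_weights <- function(pos, sigma, normalize = TRUE) {
  n <- length(pos)
  lo <- findInterval(pos - 4 * sigma, pos, left.open = TRUE) + 1L
  hi <- findInterval(pos + 4 * sigma, pos)
  idx_i <- rep.int(seq_len(n), hi - lo + 1L)
  idx_j <- unlist(lapply(seq_len(n), function(i) lo[i]:hi[i]), use.names = FALSE)
  w <- exp(-((pos[idx_i] - pos[idx_j])^2) / (2 * sigma^2))
  W <- Matrix::sparseMatrix(i = idx_i, j = idx_j, x = w, dims = c(n, n))
  if (normalize) W <- Matrix::Diagonal(x = 1 / Matrix::rowSums(W)) %*% W
  W
}

#' Exact binomial test of linkage at individually scored SNPs
#'
#' Tests whether `k` of `n` segregants carrying the superior allele deviates
#' from the Mendelian 1/2, with the exact two-sided p-value (the summed
#' probability of all outcomes no more likely than the observed one).
#'
#' @param k successes: segregants carrying the superior allele (vectorised).
#' @param n trials: segregants scored (vectorised along `k`).
#' @return a `data.frame` of class `linkage_test` with columns `k`, `n`,
#'   `p_value`, `direction` (`"superior"`, `"inferior"` or `"none"`).
#' @export
binomial_linkage_test <- function(k, n) {
  if (any(n < 1)) stop("n must be >= 1")
  stopifnot(length(k) == length(n) || length(n) == 1L)
  n <- rep_len(n, length(k))
  if (any(k < 0 | k > n)) stop("k must lie in [0, n]")
  p <- vapply(seq_along(k), function(i)
    stats::binom.test(k[i], n[i], p = 0.5)$p.value, numeric(1))
  dir <- ifelse(k * 2 > n, "superior", ifelse(k * 2 < n, "inferior", "none"))
  out <- data.frame(k = k, n = n, p_value = p, direction = dir)
  class(out) <- c("linkage_test", "data.frame")
  out
}

#' Call QTL intervals where the smoothed band excludes 0.5
#'
#' Maximal runs of consecutive covered markers whose confidence band lies
#' entirely above (superior linkage) or below (inferior linkage) 0.5 become
#' intervals. Boundaries are the first and last markers of the run, i.e.
#' marker-anchored; the peak is the marker with the most extreme fit.
#'
#' @param curve a [smooth_frequencies()] result.
#' @param alpha significance level; when it differs from the level the curve
#'   was built with, the band is re-formed from the stored logit standard
#'   errors.
#' @return a `data.frame` of class `qtl_intervals` with columns `chrom`,
#'   `start`, `end` (1-based inclusive), `peak`, `direction`, `peak_fit`,
#'   `evidence`.
#' @export
call_qtl_intervals <- function(curve, alpha = 0.05) {
  stopifnot(inherits(curve, "smoothed_curve"))
  if (!identical(alpha, attr(curve, "alpha"))) {
    z <- stats::qnorm(1 - alpha / 2)
    lg <- stats::qlogis(curve$fit)
    curve$lower <- stats::plogis(lg - z * curve$se_logit)
    curve$upper <- stats::plogis(lg + z * curve$se_logit)
  }
  rows <- list()
  for (c in unique(curve$chrom)) {
    cc <- curve[curve$chrom == c, , drop = FALSE]
    for (dir in c("superior", "inferior")) {
      hit <- if (dir == "superior") cc$lower > 0.5 else cc$upper < 0.5
      runs <- true_runs(hit)
      if (nrow(runs) == 0L) next
      for (r in seq_len(nrow(runs))) {
        seg <- cc[runs[r, 1]:runs[r, 2], , drop = FALSE]
        pk <- if (dir == "superior") which.max(seg$fit) else which.min(seg$fit)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = c, start = min(seg$pos), end = max(seg$pos),
          peak = seg$pos[pk], direction = dir, peak_fit = seg$fit[pk],
          evidence = "pooled")
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               peak = numeric(), direction = character(),
               peak_fit = numeric(), evidence = character())
  out <- out[order(match(out$chrom, unique(curve$chrom)), out$start), ]
  rownames(out) <- NULL
  class(out) <- c("qtl_intervals", "data.frame")
  out
}

#' Remove linkage also present in an unselected control pool
#'
#' Portions of selected-pool intervals overlapped by a same-direction
#' unselected-pool interval are excised (they reflect inadvertent selection
#' by the breeding protocol rather than the trait); empty remnants are
#' dropped. Peaks falling inside an excised portion become `NA`.
#'
#' @param selected,unselected `qtl_intervals` data.frames on the same genome.
#' @return a `qtl_intervals` data.frame.
#' @export
subtract_unselected <- function(selected, unselected) {
  if (nrow(selected) == 0L || nrow(unselected) == 0L) return(selected)
  rows <- list()
  for (i in seq_len(nrow(selected))) {
    s <- selected[i, ]
    u <- unselected[unselected$chrom == s$chrom &
                      unselected$direction == s$direction, , drop = FALSE]
    keep <- IRanges::IRanges(start = s$start, end = s$end)
    if (nrow(u) > 0L)
      keep <- IRanges::setdiff(keep, IRanges::IRanges(u$start, u$end))
    if (length(keep) == 0L) next
    for (j in seq_len(length(keep))) {
      r <- s
      r$start <- IRanges::start(keep)[j]
      r$end <- IRanges::end(keep)[j]
      if (is.na(r$peak) || r$peak < r$start || r$peak > r$end) {
        r$peak <- NA_real_
        r$peak_fit <- NA_real_
      }
      rows[[length(rows) + 1L]] <- r
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else selected[0, ]
  rownames(out) <- NULL
  class(out) <- c("qtl_intervals", "data.frame")
  out
}

## Fitting-function front end ------------------------------------------------

#' Map QTLs from a pooled-segregant allele-count sample
#'
#' The pooled-segregant engine end to end: quality filtering, SNP variant
#' frequency, genome smoothing with a confidence band, deviation-from-0.5
#' interval calling, and optional subtraction of linkage found in an
#' unselected control pool.
#'
#' @param counts an [allele_counts()] holding the selected pool (and
#'   optionally the unselected pool) as samples.
#' @param sample label or index of the selected-pool sample.
#' @param unselected optional label/index of an unselected control pool.
#' @param min_coverage,min_quality quality thresholds (defaults 15 reads,
#'   PHRED 35).
#' @param bandwidth smoothing bandwidth in bp (default 20000).
#' @param alpha band level for interval calling.
#' @param pool_size segregants per pool, passed to [smooth_frequencies()]
#'   (`NULL` = read-sampling error only).
#' @return an object of class `pooled_qtl` with components `frequency`,
#'   `curve`, `intervals` (control-subtracted when a control is given),
#'   `intervals_raw`, `control_intervals`, `params`.
#' @seealso [map_individual_qtl()] for the individual-segregant engine.
#' @export
map_pooled_qtl <- function(counts, sample = 1L, unselected = NULL,
                           min_coverage = 15, min_quality = 35,
                           bandwidth = 20000, alpha = 0.05,
                           pool_size = NULL) {
  filtered <- quality_filter(counts, min_coverage, min_quality)
  freq <- variant_frequency(filtered, sample)
  curve <- smooth_frequencies(freq, bandwidth = bandwidth, alpha = alpha,
                              pool_size = pool_size)
  intervals <- call_qtl_intervals(curve, alpha = alpha)
  ctrl <- NULL
  final <- intervals
  if (!is.null(unselected)) {
    cfreq <- variant_frequency(filtered, unselected)
    ccurve <- smooth_frequencies(cfreq, bandwidth = bandwidth,
                                 alpha = alpha, pool_size = pool_size)
    ctrl <- call_qtl_intervals(ccurve, alpha = alpha)
    final <- subtract_unselected(intervals, ctrl)
  }
  structure(list(frequency = freq, curve = curve, intervals = final,
                 intervals_raw = intervals, control_intervals = ctrl,
                 params = list(sample = sample, unselected = unselected,
                               min_coverage = min_coverage,
                               min_quality = min_quality,
                               bandwidth = bandwidth, alpha = alpha,
                               pool_size = pool_size)),
            class = "pooled_qtl")
}

#' @export
print.pooled_qtl <- function(x, ...) {
  cat("Pooled-segregant QTL map\n")
  cat("  markers:", sum(!is.na(x$frequency$f)), "covered of",
      nrow(x$frequency), "\n")
  cat("  bandwidth:", attr(x$curve, "bandwidth"), "bp  alpha:",
      x$params$alpha, "\n")
  cat("  intervals called:", nrow(x$intervals),
      if (!is.null(x$control_intervals)) "(control-subtracted)" else "", "\n")
  invisible(x)
}

#' @export
summary.pooled_qtl <- function(object, ...) {
  cat("Pooled-segregant QTL map:", nrow(object$intervals), "interval(s)\n")
  if (nrow(object$intervals) > 0L) {
    df <- object$intervals
    df$width_kb <- round_kb(df$end - df$start)
    print.data.frame(df, row.names = FALSE)
  }
  invisible(object$intervals)
}

#' @export
coef.pooled_qtl <- function(object, ...) object$intervals

#' Plot a pooled-segregant QTL map
#'
#' Per-chromosome panels of raw variant frequencies, the smoothed curve, its
#' confidence band and the 0.5 reference line; called intervals are shaded.
#'
#' @param x a `pooled_qtl` object.
#' @param chroms chromosomes to draw (default all).
#' @param ... unused.
#' @export
plot.pooled_qtl <- function(x, chroms = NULL, ...) {
  if (is.null(chroms)) chroms <- unique(x$curve$chrom)
  old <- graphics::par(mfrow = c(length(chroms), 1),
                       mar = c(3.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (c in chroms) {
    f <- x$frequency[x$frequency$chrom == c, ]
    s <- x$curve[x$curve$chrom == c, ]
    plot(f$pos, f$f, pch = 16, cex = 0.3, col = "grey60",
         ylim = c(0, 1), xlab = "position (bp)",
         ylab = "variant frequency", main = c)
    iv <- x$intervals[x$intervals$chrom == c, ]
    if (nrow(iv) > 0L)
      graphics::rect(iv$start, 0, iv$end, 1,
                     col = grDevices::adjustcolor("gold", 0.3), border = NA)
    graphics::polygon(c(s$pos, rev(s$pos)), c(s$lower, rev(s$upper)),
                      col = grDevices::adjustcolor("steelblue", 0.3),
                      border = NA)
    graphics::lines(s$pos, s$fit, col = "steelblue4", lwd = 2)
    graphics::abline(h = 0.5, lty = 2)
  }
  invisible(x)
}
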
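## Individual-segregant QTL mapping: Kullback-Leibler parent-of-origin

#' Pseudocounted genotype distribution at a SNP
#'
#' Converts allele read counts into a probability distribution over the two
#' parental alleles, `p = (count + alpha) / (total + 2 alpha)`. The
#' pseudocount keeps parental distributions off the simplex boundary so that
#' Kullback-Leibler divergences stay finite; zero coverage yields the
#' uninformative uniform distribution.
#'
#' @param sup,inf numeric superior/inferior allele read counts (vectors or
#'   matrices; `NA` counts are treated as zero coverage).
#' @param alpha pseudocount (> 0, default 1).
#' @return list with elements `p_sup` and `p_inf` (same shape as the input),
#'   each in (0, 1), summing to 1.
#' @export
genotype_distribution <- function(sup, inf, alpha = 1) {
  stopifnot(alpha > 0)
  sup[is.na(sup)] <- 0
  inf[is.na(inf)] <- 0
  tot <- sup + inf
  p_sup <- (sup + alpha) / (tot + 2 * alpha)
  list(p_sup = p_sup, p_inf = 1 - p_sup)
}

#' Kullback-Leibler divergence between two-point distributions
#'
#' `D(p || q)` in nats for Bernoulli distributions given by their
#' superior-allele probabilities (vectorised). Non-negative, zero iff
#' `p == q`.
#'
#' @param p,q probabilities in (0, 1).
#' @return numeric divergences.
#' @export
kl_divergence <- function(p, q) {
  p * log(p / q) + (1 - p) * log((1 - p) / (1 - q))
}

kl2 <- kl_divergence

#' Kullback-Leibler parent-of-origin assignment at SNPs
#'
#' For each SNP of a segregant, computes the KL divergence of the segregant's
#' genotype distribution to each parental distribution and assigns the SNP to
#' the parent with the smaller divergence. The signed score
#' `D_inferior - D_superior` is positive when the superior parent's genotype
#' explains the reads better. An exact binomial tail probability of the
#' observed reads under the non-assigned parent's genotype distribution (its
#' own error model) quantifies assignment confidence.
#'
#' @param seg_sup,seg_inf segregant allele counts (vector or matrix, SNP x
#'   segregant).
#' @param parent_sup,parent_inf parental allele counts at the same SNPs: each
#'   a list or two-column structure; simplest is a list with `sup` and `inf`
#'   count vectors for that parent's own sequencing sample.
#' @param alpha pseudocount passed to [genotype_distribution()].
#' @return a list of class `divergence_record`: matrices/vectors `d_sup`,
#'   `d_inf` (nats, >= 0), `score` (`d_inf - d_sup`), `assignment` (+1
#'   superior, -1 inferior, 0 undetermined), `p_value`.
#' @export
kl_assign <- function(seg_sup, seg_inf, parent_sup, parent_inf, alpha = 1) {
  g <- genotype_distribution(seg_sup, seg_inf, alpha)
  gp <- genotype_distribution(parent_sup$sup, parent_sup$inf, alpha)
  gq <- genotype_distribution(parent_inf$sup, parent_inf$inf, alpha)
  d_sup <- kl2(g$p_sup, gp$p_sup)
  d_inf <- kl2(g$p_sup, gq$p_sup)
  score <- d_inf - d_sup
  # equal divergences are undetermined; the tolerance absorbs floating-point
  # asymmetry of the two KL sums
  assignment <- sign(score) * (abs(score) > 1e-12)
  # confidence: reads of the assigned allele under the rival parent's model
  ns <- replace(seg_sup, is.na(seg_sup), 0)
  ni <- replace(seg_inf, is.na(seg_inf), 0)
  n <- ns + ni
  # null success prob: rival parent's probability of the assigned allele
  p_null <- ifelse(assignment >= 0, gq$p_sup, 1 - gp$p_sup)
  k_obs <- ifelse(assignment >= 0, ns, ni)
  p_value <- stats::pbinom(k_obs - 1, n, p_null, lower.tail = FALSE)
  p_value[n == 0] <- 1
  structure(list(d_sup = d_sup, d_inf = d_inf, score = score,
                 assignment = assignment, p_value = p_value),
            class = "divergence_record")
}

#' False-discovery-rate filter on parent-of-origin assignments
#'
#' Benjamini-Hochberg correction of the per-SNP assignment p-values, applied
#' within each segregant separately; assignments whose adjusted p-value
#' exceeds `q` are set undetermined (score and assignment zeroed). The
#' step-up rule is inclusive: an adjusted p-value exactly at `q` survives.
#'
#' @param records a [kl_assign()] result.
#' @param q FDR level in (0, 1); the default 0.007 is a conservative level
#'   accounting for the many samples scored in parallel.
#' @return the records with added `p_adjusted` and with failing assignments
#'   set undetermined.
#' @export
fdr_filter <- function(records, q = 0.007) {
  stopifnot(q > 0, q < 1)
  p <- as.matrix(records$p_value)
  padj <- apply(p, 2L, stats::p.adjust, method = "BH")
  fail <- padj > q
  records$p_adjusted <- array(padj, dim = dim(p))
  records$assignment <- replace(records$assignment, fail, 0)
  records$score <- replace(records$score, fail, 0)
  records
}

#' Gaussian smoothing of signed scores along a chromosome
#'
#' Kernel regression over genomic coordinates: each SNP's smoothed value is
#' the normalised Gaussian-weighted mean of neighbouring SNP scores
#' (truncated at four standard deviations), correcting for sequencing
#' error/bias spikes. Constant input is returned unchanged.
#'
#' @param pos SNP positions (bp) on one chromosome, sorted.
#' @param scores numeric vector (or SNP x segregant matrix) of signed scores.
#' @param sigma kernel standard deviation in bp (default 1000).
#' @return smoothed scores, same shape as `scores`.
#' @export
gaussian_smooth <- function(pos, scores, sigma = 1000) {
  stopifnot(sigma > 0, !is.unsorted(pos))
  W <- kernel_weights(pos, sigma)
  sm <- as.matrix(W %*% as.matrix(scores))
  if (is.matrix(scores)) sm else as.numeric(sm)
}

#' Ternary parent-of-origin window calls for segregants
#'
#' Tiles each chromosome with non-overlapping windows anchored at position 1,
#' sums the smoothed signed scores of the SNPs inside each window, and calls
#' the window `+1` (superior parent) when the sum exceeds `tau`, `-1`
#' (inferior parent) below `-tau`, and `0` (undetermined) otherwise —
#' including windows without any surviving SNP.
#'
#' @param markers `marker_table` rows matching the score rows.
#' @param scores smoothed signed scores (SNP x segregant matrix or vector).
#' @param layout the [genome_layout()] (fixes window tiling per chromosome).
#' @param window window width in bp (default 3000).
#' @param tau minimum absolute window sum to call a parent (default 0: the
#'   sign decides, zero sums are undetermined).
#' @return an object of class `poo_track`: per chromosome a list with
#'   `start`, `end` (window coordinates, 1-based inclusive) and `calls`
#'   (window x segregant integer matrix in {-1, 0, +1}).
#' @export
window_calls <- function(markers, scores, layout, window = 3000, tau = 0) {
  stopifnot(window > 0, tau >= 0)
  scores <- as.matrix(scores)
  out <- list()
  for (i in seq_along(layout$chrom)) {
    c <- layout$chrom[i]
    L <- layout$lengths[i]
    n_win <- ceiling(L / window)
    starts <- (seq_len(n_win) - 1L) * window + 1
    ends <- pmin(starts + window - 1, L)
    idx <- which(markers$chrom == c)
    calls <- matrix(0L, n_win, ncol(scores))
    if (length(idx) > 0L) {
      wid <- (markers$pos[idx] - 1) %/% window + 1
      sums <- rowsum(scores[idx, , drop = FALSE], group = wid)
      gw <- as.integer(rownames(sums))
      cm <- matrix(0, n_win, ncol(scores))
      cm[gw, ] <- sums
      calls[cm > tau] <- 1L
      calls[cm < -tau] <- -1L
    }
    out[[c]] <- list(start = starts, end = ends, calls = calls)
  }
  structure(out, class = "poo_track")
}

#' Average parent-of-origin tracks over the top-ranked segregants
#'
#' Per window, the arithmetic mean of the ternary calls of the `k`
#' highest-phenotype segregants, the phenotype-ordered averaging step that
#' turns individual tracks into a population linkage map.
#'
#' @param track a [window_calls()] result (all segregants).
#' @param ranking integer vector ordering segregant columns from most to
#'   least extreme phenotype.
#' @param k number of top segregants to average (`1 <= k <=` columns).
#' @return an object of class `avg_track`: per chromosome `start`, `end`,
#'   `value` (in `[-1, 1]`); attribute `k`.
#' @export
phenotype_ordered_average <- function(track, ranking, k) {
  n_seg <- ncol(track[[1]]$calls)
  if (k < 1 || k > n_seg) stop("k out of range")
  stopifnot(length(ranking) == n_seg)
  top <- ranking[seq_len(k)]
  out <- lapply(track, function(t)
    list(start = t$start, end = t$end,
         value = rowMeans(t$calls[, top, drop = FALSE])))
  attr(out, "k") <- k
  class(out) <- "avg_track"
  out
}

#' Call QTL intervals from an averaged parent-of-origin track
#'
#' Maximal runs of windows whose averaged value is strictly above
#' `threshold` (superior linkage) or strictly below `-threshold` (inferior
#' linkage) are merged into intervals; a window exactly at the threshold is
#' not called.
#'
#' @param avg a [phenotype_ordered_average()] result.
#' @param threshold call threshold in (0, 1] (default 0.7).
#' @return a `qtl_intervals` data.frame (`evidence = "individual"`).
#' @export
call_qtls_from_average <- function(avg, threshold = 0.7) {
  stopifnot(threshold > 0, threshold <= 1)
  rows <- list()
  for (c in names(avg)) {
    t <- avg[[c]]
    for (dir in c("superior", "inferior")) {
      hit <- if (dir == "superior") t$value > threshold else
        t$value < -threshold
      runs <- true_runs(hit)
      if (nrow(runs) == 0L) next
      for (r in seq_len(nrow(runs))) {
        win <- runs[r, 1]:runs[r, 2]
        pk <- win[if (dir == "superior") which.max(t$value[win]) else
          which.min(t$value[win])]
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = c, start = t$start[runs[r, 1]], end = t$end[runs[r, 2]],
          peak = (t$start[pk] + t$end[pk]) / 2, direction = dir,
          peak_fit = t$value[pk], evidence = "individual")
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               peak = numeric(), direction = character(),
               peak_fit = numeric(), evidence = character())
  rownames(out) <- NULL
  class(out) <- c("qtl_intervals", "data.frame")
  out
}

#' Per-SNP binomial linkage p-values from individual genotype assignments
#'
#' At each SNP, the determined parent-of-origin assignments across segregants
#' form the trials of an exact binomial test against the Mendelian 1/2
#' (successes = superior assignments). SNPs with no determined assignment
#' are omitted.
#'
#' @param markers `marker_table` rows matching the assignment rows.
#' @param assignment SNP x segregant matrix in {-1, 0, +1} (e.g. the
#'   `assignment` element of a filtered [kl_assign()] record).
#' @return a `data.frame` with columns `chrom`, `pos`, `k`, `n`, `p_value`,
#'   `direction`.
#' @export
per_snp_binomial_pvalues <- function(markers, assignment) {
  assignment <- as.matrix(assignment)
  n <- rowSums(assignment != 0)
  k <- rowSums(assignment == 1)
  keep <- n > 0
  if (!any(keep))
    return(data.frame(chrom = character(), pos = numeric(), k = integer(),
                      n = integer(), p_value = numeric(),
                      direction = character()))
  lt <- binomial_linkage_test(k[keep], n[keep])
  data.frame(chrom = markers$chrom[keep], pos = markers$pos[keep],
             k = lt$k, n = lt$n, p_value = lt$p_value,
             direction = lt$direction)
}

## Fitting-function front end ------------------------------------------------

#' Map QTLs from individually sequenced segregants
#'
#' The individual-segregant engine end to end: quality filtering,
#' pseudocounted genotype distributions, Kullback-Leibler parent-of-origin
#' assignment against the two sequenced parents, per-segregant FDR
#' filtering, Gaussian smoothing of the signed scores, ternary 3-kb window
#' calls, phenotype-ordered averaging over the `k` most extreme segregants,
#' and threshold calling at the averaged track.
#'
#' @param counts an [allele_counts()] with one sample per segregant.
#' @param parent_sup,parent_inf lists with `sup`/`inf` count vectors for the
#'   superior and inferior parent samples at the same markers.
#' @param layout the [genome_layout()].
#' @param ranking integer vector ordering segregants from most to least
#'   extreme phenotype (default: column order).
#' @param k segregants averaged (default: all).
#' @param min_coverage,min_quality quality thresholds (defaults 15, 35).
#' @param alpha pseudocount for genotype distributions (default 1).
#' @param fdr_q per-segregant FDR level (default 0.007).
#' @param sigma Gaussian smoothing bandwidth in bp (default 1000).
#' @param window window width in bp (default 3000).
#' @param tau minimum window evidence (default 0).
#' @param threshold averaged-track call threshold (default 0.7).
#' @return an object of class `indiv_qtl` with components `records`,
#'   `tracks`, `average`, `intervals`, `snp_pvalues`, `params`.
#' @seealso [map_pooled_qtl()] for the pooled engine.
#' @export
map_individual_qtl <- function(counts, parent_sup, parent_inf, layout,
                               ranking = NULL, k = NULL,
                               min_coverage = 15, min_quality = 35,
                               alpha = 1, fdr_q = 0.007, sigma = 1000,
                               window = 3000, tau = 0, threshold = 0.7) {
  filtered <- quality_filter(counts, min_coverage, min_quality)
  n_seg <- length(filtered$samples)
  if (is.null(ranking)) ranking <- seq_len(n_seg)
  if (is.null(k)) k <- n_seg
  rec <- kl_assign(filtered$sup, filtered$inf, parent_sup, parent_inf,
                   alpha = alpha)
  rec <- fdr_filter(rec, q = fdr_q)
  smoothed <- rec$score
  for (c in unique(filtered$markers$chrom)) {
    idx <- which(filtered$markers$chrom == c)
    if (length(idx) > 1L)
      smoothed[idx, ] <- gaussian_smooth(filtered$markers$pos[idx],
                                         rec$score[idx, , drop = FALSE],
                                         sigma = sigma)
  }
  tracks <- window_calls(filtered$markers, smoothed, layout,
                         window = window, tau = tau)
  avg <- phenotype_ordered_average(tracks, ranking, k)
  intervals <- call_qtls_from_average(avg, threshold = threshold)
  snp_p <- per_snp_binomial_pvalues(filtered$markers, rec$assignment)
  structure(list(records = rec, smoothed = smoothed, tracks = tracks,
                 average = avg, intervals = intervals, snp_pvalues = snp_p,
                 params = list(k = k, ranking = ranking, alpha = alpha,
                               fdr_q = fdr_q, sigma = sigma, window = window,
                               tau = tau, threshold = threshold,
                               min_coverage = min_coverage,
                               min_quality = min_quality)),
            class = "indiv_qtl")
}

#' @export
print.indiv_qtl <- function(x, ...) {
  cat("Individual-segregant QTL map (Kullback-Leibler parent-of-origin)\n")
  cat("  segregants:", ncol(as.matrix(x$records$score)),
      "  averaged over top", x$params$k, "\n")
  cat("  sigma:", x$params$sigma, "bp  window:", x$params$window,
      "bp  FDR q:", x$params$fdr_q, "  call threshold: ±",
      x$params$threshold, "\n")
  cat("  intervals called:", nrow(x$intervals), "\n")
  invisible(x)
}

#' @export
summary.indiv_qtl <- function(object, ...) {
  cat("Individual-segregant QTL map:", nrow(object$intervals),
      "interval(s)\n")
  if (nrow(object$intervals) > 0L) {
    df <- object$intervals
    df$width_kb <- round_kb(df$end - df$start)
    print.data.frame(df, row.names = FALSE)
  }
  invisible(object$intervals)
}

#' @export
coef.indiv_qtl <- function(object, ...) object$intervals

#' Plot an averaged parent-of-origin linkage track
#'
#' Per-chromosome step plot of the averaged ternary track with the call
#' thresholds marked.
#'
#' @param x an `indiv_qtl` object.
#' @param chroms chromosomes to draw (default all).
#' @param ... unused.
#' @export
plot.indiv_qtl <- function(x, chroms = NULL, ...) {
  if (is.null(chroms)) chroms <- names(x$average)
  old <- graphics::par(mfrow = c(length(chroms), 1),
                       mar = c(3.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  thr <- x$params$threshold
  for (c in chroms) {
    t <- x$average[[c]]
    mid <- (t$start + t$end) / 2
    plot(mid, t$value, type = "s", ylim = c(-1, 1), col = "darkgreen",
         xlab = "position (bp)", ylab = "mean parent-of-origin", main = c)
    graphics::abline(h = c(-thr, 0, thr), lty = c(3, 2, 3))
  }
  invisible(x)
}
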
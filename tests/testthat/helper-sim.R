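# Shared fixtures: small layouts and populations built in code.

tiny_layout <- function(n_chr = 2, len = 3e5, cm_per_kb = 0.35) {
  genome_layout(stats::setNames(rep(len, n_chr), paste0("chr", 1:n_chr)),
                cm_per_kb = cm_per_kb)
}

# a hand-built mosaic: one chromosome per element of `labels`, whole
# chromosome from one parent
pure_mosaic <- function(layout, labels) {
  segs <- lapply(seq_along(layout$chrom), function(i)
    list(ends = layout$lengths[[i]], labels = as.integer(labels[i])))
  names(segs) <- layout$chrom
  structure(segs, class = "haplo_mosaic")
}

# quick F1 population from the standard superior x inferior cross
quick_population <- function(layout, n = 96, seed = 1) {
  f0 <- cross(founder_mosaic(layout, "superior"),
              founder_mosaic(layout, "inferior"))
  inbreed(list(f0), 0L, layout, pop_size = n, seed = seed)
}

# exact two-sided binomial p-value by exhaustive enumeration of all n + 1
# outcomes (independent oracle for the linkage test)
enum_binom_p <- function(k, n) {
  d <- stats::dbinom(0:n, n, 0.5)
  sum(d[d <= d[k + 1] * (1 + 1e-12)])
}

# brute-force Benjamini-Hochberg step-up: returns logical keep vector
bh_keep_oracle <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  pass <- which(ps <= q * seq_len(m) / m)
  keep <- rep(FALSE, m)
  if (length(pass)) keep[ord[seq_len(max(pass))]] <- TRUE
  keep
}

# direct O(n^2) kernel regression with the same truncated-Gaussian kernel
# definition, written naively as the smoothing oracle
smooth_oracle <- function(pos, scores, sigma) {
  n <- length(pos)
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- exp(-((pos[i] - pos)^2) / (2 * sigma^2))
    w[abs(pos[i] - pos) > 4 * sigma] <- 0
    out[i] <- sum(w * scores) / sum(w)
  }
  out
}
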
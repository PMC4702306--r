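make_counts <- function(chrom, pos, sup, inf, qual = 37, sample = "pool") {
  mk <- data.frame(chrom = chrom, pos = pos,
                   sup_allele = rep_len("A", length(pos)),
                   inf_allele = rep_len("C", length(pos)))
  class(mk) <- c("marker_table", "data.frame")
  allele_counts(mk, sup, inf, rep_len(qual, length(pos)), sample)
}

test_that("quality filtering masks on inclusive thresholds", {
  pc <- make_counts("c1", c(100, 200, 300, 400),
                    sup = c(7, 8, 20, 20), inf = c(7, 7, 0, 10),
                    qual = c(37, 37, 34.9, 35))
  filt <- quality_filter(pc, min_coverage = 15, min_quality = 35)
  expect_true(is.na(filt$sup[1, 1]))      # coverage 14: masked
  expect_false(is.na(filt$sup[2, 1]))     # coverage 15: retained
  expect_true(is.na(filt$sup[3, 1]))      # quality 34.9: masked
  expect_false(is.na(filt$sup[4, 1]))     # quality 35: retained
  empty <- make_counts(character(), numeric(), numeric(), numeric())
  expect_equal(nrow(quality_filter(empty)$markers), 0L)
})

test_that("variant frequency is the superior-read fraction", {
  pc <- make_counts("c1", c(100, 200, 300), sup = c(14, 28, 0),
                    inf = c(14, 0, 0))
  f <- variant_frequency(pc, 1L)
  expect_equal(f$f, c(0.5, 1, NA_real_))
  expect_error(variant_frequency(pc, "nope"), "unknown sample")
})

test_that("smoothing preserves a constant signal exactly", {
  n <- 60
  pc <- make_counts("c1", seq(5000, by = 5000, length.out = n),
                    sup = rep(10, n), inf = rep(10, n))
  curve <- smooth_frequencies(variant_frequency(pc, 1L), bandwidth = 20000)
  expect_equal(curve$fit, rep(0.5, n))
  expect_true(all(curve$lower <= curve$fit & curve$fit <= curve$upper))
  expect_true(all(curve$fit >= 0 & curve$fit <= 1))
})

test_that("infinite bandwidth approaches the coverage-weighted mean", {
  set.seed(2)
  n <- 40
  sup <- rbinom(n, 40, 0.7)
  pc <- make_counts("c1", sort(sample.int(2e5, n)), sup = sup,
                    inf = 40 - sup)
  curve <- smooth_frequencies(variant_frequency(pc, 1L), bandwidth = 1e9)
  expect_equal(curve$fit, rep((sum(sup) + 0.5) / (40 * n + 1), n),
               tolerance = 1e-6)
})

test_that("a single-marker chromosome yields its own binomial band", {
  pc <- make_counts(c("c1", "c2", "c2"), c(100, 100, 200),
                    sup = c(30, 10, 10), inf = c(10, 10, 10))
  curve <- smooth_frequencies(variant_frequency(pc, 1L), bandwidth = 500)
  one <- curve[curve$chrom == "c1", ]
  expect_equal(nrow(one), 1L)
  expect_equal(one$fit, 30.5 / 41)
  expect_true(one$lower < one$fit & one$fit < one$upper)
})

test_that("smoothed step signal peaks inside the elevated region", {
  set.seed(7)
  pos <- seq(1000, 3e5, by = 1000)
  inside <- pos >= 1e5 & pos <= 1.4e5
  depth <- 50
  sup <- rbinom(length(pos), depth, ifelse(inside, 0.95, 0.5))
  pc <- make_counts("c1", pos, sup, depth - sup)
  fit <- map_pooled_qtl(pc, bandwidth = 10000)
  expect_gte(nrow(fit$intervals), 1L)
  top <- fit$intervals[which.max(fit$intervals$peak_fit), ]
  expect_true(top$peak >= 1e5 && top$peak <= 1.4e5)
  expect_identical(top$direction, "superior")
})

test_that("exact binomial p-values match exhaustive enumeration", {
  for (n in c(1, 5, 13, 27, 30)) {
    res <- binomial_linkage_test(0:n, n)
    oracle <- vapply(0:n, enum_binom_p, numeric(1), n = n)
    expect_equal(res$p_value, oracle, tolerance = 1e-12)
  }
  # closed forms at n = 27
  res27 <- binomial_linkage_test(c(27L, 14L, 0L), 27L)
  expect_equal(res27$p_value[1], 2 * 0.5^27, tolerance = 1e-12)
  expect_gt(res27$p_value[2], 0.99)
  expect_equal(res27$p_value[3], res27$p_value[1])   # null symmetry
  expect_identical(res27$direction, c("superior", "superior", "inferior"))
  expect_error(binomial_linkage_test(0L, 0L), "n must be")
})

test_that("interval calling respects the band and the sign convention", {
  n <- 50
  pc <- make_counts("c1", seq(2000, by = 2000, length.out = n),
                    sup = rep(10, n), inf = rep(10, n))
  curve <- smooth_frequencies(variant_frequency(pc, 1L), bandwidth = 10000)
  expect_equal(nrow(call_qtl_intervals(curve)), 0L)   # band holds 0.5
  pc2 <- make_counts("c1", seq(2000, by = 2000, length.out = n),
                     sup = rep(38, n), inf = rep(2, n))
  iv <- call_qtl_intervals(smooth_frequencies(variant_frequency(pc2, 1L),
                                              bandwidth = 10000))
  expect_equal(nrow(iv), 1L)
  expect_identical(iv$direction, "superior")
  expect_gt(iv$peak_fit, 0.5)
})

test_that("unselected-pool subtraction matches a per-base oracle", {
  mk_iv <- function(chrom, start, end, dir) {
    structure(data.frame(chrom = chrom, start = start, end = end,
                         peak = (start + end) / 2, direction = dir,
                         peak_fit = 0.9, evidence = "pooled"),
              class = c("qtl_intervals", "data.frame"))
  }
  sel <- mk_iv("c1", 100, 200, "superior")
  # disjoint: unchanged
  expect_equal(subtract_unselected(sel, mk_iv("c1", 300, 400, "superior")),
               sel)
  # identical: empty
  expect_equal(nrow(subtract_unselected(sel, sel)), 0L)
  # opposite direction: unchanged
  expect_equal(nrow(subtract_unselected(sel, mk_iv("c1", 100, 200,
                                                   "inferior"))), 1L)
  # spec worked example
  out <- subtract_unselected(sel, mk_iv("c1", 150, 250, "superior"))
  expect_equal(c(out$start, out$end), c(100, 149))
  # randomised property vs brute-force base sets
  set.seed(5)
  for (i in 1:20) {
    s <- sort(sample.int(500, 2)); u <- sort(sample.int(500, 2))
    sel_i <- mk_iv("c1", s[1], s[2], "superior")
    uns_i <- mk_iv("c1", u[1], u[2], "superior")
    out_i <- subtract_unselected(sel_i, uns_i)
    bases <- setdiff(seq(s[1], s[2]), seq(u[1], u[2]))
    got <- if (nrow(out_i)) unlist(lapply(seq_len(nrow(out_i)), function(j)
      seq(out_i$start[j], out_i$end[j]))) else integer(0)
    expect_identical(sort(got), sort(bases))
  }
})

test_that("the pooled fit object prints and summarises", {
  set.seed(3)
  pos <- seq(2000, 2e5, by = 2000)
  sup <- rbinom(length(pos), 40, 0.5)
  pc <- make_counts("c1", pos, sup, 40 - sup)
  fit <- map_pooled_qtl(pc)
  expect_s3_class(fit, "pooled_qtl")
  expect_output(print(fit), "Pooled-segregant")
  expect_identical(coef(fit), fit$intervals)
})
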
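test_that("genotype distributions follow the pseudocount formula", {
  g <- genotype_distribution(c(10, 0, 5), c(0, 0, 5), alpha = 1)
  expect_equal(g$p_sup, c(11 / 12, 0.5, 0.5))
  expect_equal(g$p_sup + g$p_inf, rep(1, 3))
  g2 <- genotype_distribution(5, 5, alpha = 0.37)
  expect_equal(g2$p_sup, 0.5)
  expect_error(genotype_distribution(1, 1, alpha = 0), "alpha")
})

test_that("KL divergence is non-negative and zero iff equal", {
  set.seed(11)
  p <- runif(200, 0.01, 0.99)
  q <- runif(200, 0.01, 0.99)
  expect_true(all(kl_divergence(p, q) >= 0))
  expect_equal(kl_divergence(p, p), rep(0, 200))
  expect_true(all(kl_divergence(p, q)[abs(p - q) > 1e-3] > 0))
})

test_that("KL assignment matches a term-by-term oracle", {
  # segregant (10,2) reads vs clean parents (10,0) and (0,10), alpha = 1
  parent_sup <- list(sup = 10, inf = 0)   # distribution (11/12, 1/12)
  parent_inf <- list(sup = 0, inf = 10)   # distribution (1/12, 11/12)
  rec <- kl_assign(10, 2, parent_sup, parent_inf, alpha = 1)
  ps <- (10 + 1) / (12 + 2)               # segregant p_sup = 11/14
  oracle_d <- function(q) ps * log(ps / q) + (1 - ps) * log((1 - ps) / (1 - q))
  expect_equal(rec$d_sup, oracle_d(11 / 12))
  expect_equal(rec$d_inf, oracle_d(1 / 12))
  expect_equal(rec$score, rec$d_inf - rec$d_sup)
  expect_identical(rec$assignment, 1)
  # self-identical distribution: zero divergence to that parent
  rec0 <- kl_assign(10, 0, parent_sup, parent_inf, alpha = 1)
  expect_equal(rec0$d_sup, 0)
  # symmetric segregant: undetermined
  recu <- kl_assign(5, 5, parent_sup, parent_inf, alpha = 1)
  expect_equal(recu$score, 0)
  expect_identical(recu$assignment, 0)
})

test_that("FDR filtering reproduces the step-up oracle", {
  p <- c(0.001, 0.004, 0.04, 0.5)
  rec <- list(d_sup = rep(0, 4), d_inf = rep(1, 4), score = rep(1, 4),
              assignment = rep(1, 4), p_value = p)
  class(rec) <- "divergence_record"
  out <- fdr_filter(rec, q = 0.007)
  keep <- bh_keep_oracle(p, 0.007)
  expect_identical(out$assignment != 0, keep)
  expect_identical(keep, c(TRUE, FALSE, FALSE, FALSE))
  # all-zero p-values: nothing filtered
  rec$p_value <- rep(0, 4)
  expect_true(all(fdr_filter(rec, 0.007)$assignment == 1))
  # a p exactly at its BH threshold survives (step-up inclusive)
  rec1 <- list(d_sup = 0, d_inf = 1, score = 1, assignment = 1,
               p_value = 0.007)
  class(rec1) <- "divergence_record"
  expect_identical(fdr_filter(rec1, 0.007)$assignment, 1)
  # randomized agreement with the oracle
  set.seed(13)
  for (i in 1:10) {
    pv <- runif(50)^3
    reci <- list(d_sup = rep(0, 50), d_inf = rep(1, 50), score = rep(1, 50),
                 assignment = rep(1, 50), p_value = pv)
    class(reci) <- "divergence_record"
    expect_identical(fdr_filter(reci, 0.05)$assignment != 0,
                     bh_keep_oracle(pv, 0.05))
  }
})

test_that("Gaussian smoothing matches the direct convolution oracle", {
  set.seed(17)
  pos <- sort(sample.int(5e4, 120))
  s <- rnorm(120)
  expect_equal(gaussian_smooth(pos, s, sigma = 1000),
               smooth_oracle(pos, s, 1000), tolerance = 1e-9)
  # constant input unchanged
  expect_equal(gaussian_smooth(pos, rep(0.7, 120), sigma = 800),
               rep(0.7, 120))
  # single nonzero interior score: total mass preserved on a regular grid
  pos2 <- seq(100, by = 100, length.out = 201)
  s2 <- numeric(201); s2[101] <- 5
  expect_equal(sum(gaussian_smooth(pos2, s2, sigma = 300)), 5,
               tolerance = 1e-6)
  expect_error(gaussian_smooth(pos, s, sigma = 0), "sigma")
})

test_that("window calls tile, sum and threshold correctly", {
  lay <- genome_layout(c(c1 = 9000))
  mk <- data.frame(chrom = "c1", pos = c(500, 1500, 3500, 8500))
  scores <- c(2, 1, -3, 0)
  tr <- window_calls(mk, scores, lay, window = 3000)
  t1 <- tr$c1
  expect_equal(t1$start, c(1, 3001, 6001))
  expect_equal(t1$end, c(3000, 6000, 9000))
  expect_identical(as.integer(t1$calls), c(1L, -1L, 0L))  # sum 3, -3, 0
  # empty windows are undetermined
  none <- window_calls(data.frame(chrom = character(), pos = numeric()),
                       matrix(numeric(), 0, 1), lay, window = 3000)
  expect_true(all(none$c1$calls == 0L))
  # minimum-evidence option
  tr2 <- window_calls(mk, scores, lay, window = 3000, tau = 3)
  expect_identical(as.integer(tr2$c1$calls), c(0L, 0L, 0L))
})

test_that("window calls recover a known mosaic at high accuracy", {
  lay <- tiny_layout(1)
  mk <- make_parental_markers(lay, 580, seed = 25)
  pop <- quick_population(lay, n = 8, seed = 26)
  sq <- sequencing_spec(mean_depth = 20, error_rate = 0.002)
  ic <- sequence_segregants(pop, mk, sq, seed = 27)
  psup <- list(sup = rep(50, nrow(mk)), inf = rep(0, nrow(mk)))
  pinf <- list(sup = rep(0, nrow(mk)), inf = rep(50, nrow(mk)))
  fit <- map_individual_qtl(ic, psup, pinf, lay, min_coverage = 1)
  truth <- sapply(pop, mosaic_alleles, markers = mk)
  t1 <- fit$tracks$chr1
  # true window label where the window is interior to one parental block
  win_truth <- matrix(NA_integer_, length(t1$start), length(pop))
  for (j in seq_along(pop)) {
    wid <- (mk$pos - 1) %/% 3000 + 1
    agg <- tapply(truth[, j], wid, function(v)
      if (all(v == 1L)) 1L else if (all(v == -1L)) -1L else NA_integer_)
    win_truth[as.integer(names(agg)), j] <- agg
  }
  det <- t1$calls != 0L & !is.na(win_truth)
  agree <- mean((t1$calls == win_truth)[det])
  expect_gte(agree, 0.99)
})

test_that("phenotype-ordered averaging matches recomputation from scratch", {
  lay <- genome_layout(c(c1 = 9000))
  calls <- matrix(c(1, 1, -1,
                    1, -1, 0,
                    0, 1, 1), nrow = 3, byrow = FALSE)
  tr <- structure(list(c1 = list(start = c(1, 3001, 6001),
                                 end = c(3000, 6000, 9000),
                                 calls = calls)), class = "poo_track")
  avg3 <- phenotype_ordered_average(tr, ranking = 1:3, k = 3)
  expect_equal(avg3$c1$value, rowMeans(calls))
  expect_equal(phenotype_ordered_average(tr, 1:3, 1)$c1$value, calls[, 1])
  # incremental consistency: k and k+1 differ only via the (k+1)-th track
  for (k in 1:2) {
    a_k <- phenotype_ordered_average(tr, 1:3, k)$c1$value
    a_k1 <- phenotype_ordered_average(tr, 1:3, k + 1)$c1$value
    expect_equal(a_k1, (a_k * k + calls[, k + 1]) / (k + 1))
  }
  expect_error(phenotype_ordered_average(tr, 1:3, 4), "out of range")
  # all-ones window averages to exactly +1
  ones <- structure(list(c1 = list(start = 1, end = 3000,
                                   calls = matrix(1, 1, 9))),
                    class = "poo_track")
  expect_equal(phenotype_ordered_average(ones, 1:9, 9)$c1$value, 1)
})

test_that("threshold calling on averaged tracks is strict at 0.7", {
  avg <- structure(list(c1 = list(start = c(1, 3001, 6001, 9001),
                                  end = c(3000, 6000, 9000, 12000),
                                  value = c(0.1, 0.78, 0.78, 0.1))),
                   class = "avg_track")
  iv <- call_qtls_from_average(avg, threshold = 0.7)
  expect_equal(nrow(iv), 1L)
  expect_equal(c(iv$start, iv$end), c(3001, 9000))
  expect_identical(iv$direction, "superior")
  # exactly at the threshold: not called
  avg$c1$value <- c(0, 0.7, -0.7, 0)
  expect_equal(nrow(call_qtls_from_average(avg, 0.7)), 0L)
  # all-zero track: no intervals
  avg$c1$value <- rep(0, 4)
  expect_equal(nrow(call_qtls_from_average(avg, 0.7)), 0L)
})

test_that("per-SNP binomial p-values use determined assignments only", {
  mk <- data.frame(chrom = "c1", pos = c(100, 200, 300))
  assign <- rbind(rep(1L, 27),                 # 27/27 superior
                  c(rep(1L, 13), rep(-1L, 14)),
                  rep(0L, 27))                 # undetermined: masked
  ps <- per_snp_binomial_pvalues(mk, assign)
  expect_equal(nrow(ps), 2L)
  expect_equal(ps$p_value[1], 2 * 0.5^27, tolerance = 1e-12)
  expect_gt(ps$p_value[2], 0.99)
  expect_false(300 %in% ps$pos)
})
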
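test_that("meiosis of a homozygous diploid returns the parent everywhere", {
  lay <- tiny_layout(2)
  p <- founder_mosaic(lay, "superior")
  mk <- make_parental_markers(lay, 200, seed = 3)
  tet <- meiosis(p, p, lay, seed = 5)
  for (sp in tet)
    expect_true(all(mosaic_alleles(sp, mk) == 1L))
})

test_that("zero map density yields unrecombined parental chromosomes", {
  lay <- tiny_layout(2, cm_per_kb = 0)
  tet <- meiosis(founder_mosaic(lay, "superior"),
                 founder_mosaic(lay, "inferior"), lay, seed = 5)
  for (sp in tet)
    for (c in lay$chrom)
      expect_length(sp[[c]]$labels, 1L)
})

test_that("crossover counts follow the Poisson expectation of the map", {
  # 300 cM genome: one chromosome, expected 3 crossovers per spore
  lay <- genome_layout(c(c1 = 300 / 0.35 * 1000), cm_per_kb = 0.35)
  ps <- founder_mosaic(lay, "superior")
  pi_ <- founder_mosaic(lay, "inferior")
  set.seed(stage_seed(99, "meiosis"))
  per_meiosis <- replicate(400, {
    tet <- meiosis(ps, pi_, lay)
    mean(vapply(tet, function(sp) length(sp$c1$labels) - 1L, integer(1)))
  })
  se <- stats::sd(per_meiosis) / sqrt(length(per_meiosis))
  expect_lt(abs(mean(per_meiosis) - 3), 3 * se)
})

test_that("tetrads segregate 2:2 at every marker of the parental cross", {
  lay <- tiny_layout(3)
  mk <- make_parental_markers(lay, 300, seed = 2)
  for (s in 1:5) {
    tet <- meiosis(founder_mosaic(lay, "superior"),
                   founder_mosaic(lay, "inferior"), lay, seed = s)
    A <- sapply(tet, mosaic_alleles, markers = mk)
    expect_true(all(rowSums(A == 1L) == 2L))
    # spores 1/2 and 3/4 are complementary
    expect_true(all(A[, 1] == -A[, 2]))
    expect_true(all(A[, 3] == -A[, 4]))
  }
})

test_that("mismatched layouts are rejected", {
  lay <- tiny_layout(2)
  other <- tiny_layout(3)
  expect_error(meiosis(founder_mosaic(lay, "superior"),
                       founder_mosaic(other, "inferior"), other, seed = 1),
               "layout")
})

test_that("inbreeding rounds shorten parental blocks monotonically", {
  lay <- tiny_layout(2)
  f0 <- cross(founder_mosaic(lay, "superior"),
              founder_mosaic(lay, "inferior"))
  mean_block <- vapply(c(0L, 3L, 6L), function(r) {
    pop <- inbreed(list(f0), r, lay, pop_size = 200, seed = 31)
    mean(vapply(pop, function(m) mean(block_lengths(m)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_block) < 0))
})

test_that("inbreed returns F1 spores at rounds = 0 and rejects empty input", {
  lay <- tiny_layout(2)
  f0 <- cross(founder_mosaic(lay, "superior"),
              founder_mosaic(lay, "inferior"))
  pop <- inbreed(list(f0), 0L, lay, pop_size = 40, seed = 4)
  expect_length(pop, 40L)
  mk <- make_parental_markers(lay, 100, seed = 1)
  f <- rowMeans(sapply(pop, mosaic_alleles, markers = mk) == 1L)
  expect_true(all(f > 0 & f < 1))  # segregating, not fixed
  expect_error(inbreed(list(), 2L, lay, pop_size = 10, seed = 1), "empty")
})

test_that("allele frequencies stay near 1/2 without selection", {
  lay <- tiny_layout(3)
  mk <- make_parental_markers(lay, 600, seed = 8)
  pop <- quick_population(lay, n = 288, seed = 12)
  f <- rowMeans(sapply(pop, mosaic_alleles, markers = mk) == 1L)
  se3 <- 3 * sqrt(0.25 / length(pop))
  expect_lt(abs(stats::median(f) - 0.5), se3)
  expect_gt(mean(abs(f - 0.5) < se3), 0.95)
})

test_that("identical seeds reproduce populations bit-for-bit", {
  lay <- tiny_layout(2)
  f0 <- cross(founder_mosaic(lay, "superior"),
              founder_mosaic(lay, "inferior"))
  a <- inbreed(list(f0), 2L, lay, pop_size = 30, seed = 77)
  b <- inbreed(list(f0), 2L, lay, pop_size = 30, seed = 77)
  expect_identical(a, b)
})
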
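test_that("null and saturating architectures give closed-form scores", {
  lay <- tiny_layout(2)
  sup <- founder_mosaic(lay, "superior")
  empty <- phenotype_spec(data.frame(chrom = character(), pos = numeric(),
                                     effect = numeric()),
                          noise_sd = 0, baseline = 2.5)
  expect_equal(assign_phenotype(sup, empty, seed = 1), 2.5)
  loci <- data.frame(chrom = c("chr1", "chr2"), pos = c(1e5, 2e5),
                     effect = c(0.4, 0.7))
  add <- phenotype_spec(loci, noise_sd = 0, baseline = 1)
  expect_equal(assign_phenotype(sup, add, seed = 1), 1 + 0.4 + 0.7)
  inf <- founder_mosaic(lay, "inferior")
  expect_equal(assign_phenotype(inf, add, seed = 1), 1)
})

test_that("redundant group members are interchangeable", {
  lay <- tiny_layout(2)
  loci <- data.frame(chrom = c("chr1", "chr2"), pos = c(1e5, 2e5),
                     effect = c(0.6, 0.6))
  spec <- phenotype_spec(loci, architecture = "redundant",
                         groups = c(1L, 1L), noise_sd = 0)
  # enumerate the four haplotype combinations (A = chr1 sup, B = chr2 sup)
  score <- function(l1, l2)
    assign_phenotype(pure_mosaic(lay, c(l1, l2)), spec, seed = 1)
  expect_equal(score(1, -1), 0.6)   # A only
  expect_equal(score(-1, 1), 0.6)   # B only
  expect_equal(score(1, 1), 0.6)    # both: max, not sum
  expect_equal(score(-1, -1), 0)    # neither
})

test_that("phenotype noise is seeded and reproducible", {
  lay <- tiny_layout(1)
  pop <- quick_population(lay, n = 10, seed = 3)
  spec <- phenotype_spec(data.frame(chrom = "chr1", pos = 1e5, effect = 1),
                         noise_sd = 0.5)
  a <- assign_phenotypes(pop, spec, seed = 9)
  b <- assign_phenotypes(pop, spec, seed = 9)
  expect_identical(a, b)
  expect_false(identical(a, assign_phenotypes(pop, spec, seed = 10)))
})

test_that("truncation selection keeps the top k with stable ties", {
  pop <- as.list(letters[1:3])
  sel <- select_top(pop, c(3, 1, 2), k = 2)
  expect_identical(unlist(sel$segregants), c("a", "c"))
  expect_identical(sel$phenotype, c(3, 2))
  whole <- select_top(pop, c(3, 1, 2), k = 3)
  expect_identical(whole$index, c(1L, 3L, 2L))
  expect_error(select_top(pop, c(3, 1, 2), k = 4), "exceeds")
  # ties broken by original order
  tie <- select_top(as.list(1:3), c(1, 1, 0), k = 1)
  expect_identical(tie$index, 1L)
})

test_that("selection signal: top segregants all carry a large-effect allele", {
  lay <- tiny_layout(2)
  pop <- quick_population(lay, n = 288, seed = 21)
  locus <- data.frame(chrom = "chr2", pos = 150000, effect = 1)
  spec <- phenotype_spec(locus, noise_sd = 0)
  ph <- assign_phenotypes(pop, spec, seed = 21)
  sel <- select_top(pop, ph, 27)
  carried <- vapply(sel$segregants, function(m)
    mosaic_alleles(m, locus) == 1L, logical(1))
  expect_true(all(carried))
})
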
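## Seeded simulation studies validating the two mapping engines against
## ground truth. Used by the test suite and by scripts/acceptance.R; problem
## sizes default to a 3-chromosome scale-down of the full design (16
## chromosomes, ~23k SNPs) that keeps replicate studies fast while preserving
## marker density, selection intensity and depth.

#' Study configuration for engine validation
#'
#' A [default_config()] scaled to 3 chromosomes of 500 kb at the full
#' experiment's SNP density (~1 per 518 bp), 288 F1 segregants with the top
#' 27 selected, mean depth 50.
#'
#' @param ... overrides passed to [default_config()].
#' @export
study_config <- function(...) {
  default_config(
    chrom_lengths = c(chrI = 5e5, chrII = 5e5, chrIII = 5e5),
    n_markers = 2900L,
    pop_size_f1 = 288L, pop_size_f7 = 288L, k_selected = 27L,
    mean_depth = 50,
    causal = data.frame(chrom = "chrII", pos = 250000, effect = 1),
    noise_sd = 0.1,
    ...)
}

interval_containing <- function(intervals, chrom, pos,
                                direction = "superior") {
  hit <- intervals$chrom == chrom & intervals$start <= pos &
    intervals$end >= pos & intervals$direction == direction
  which(hit)
}

#' Parameter-recovery study: do the engines find a planted causal locus?
#'
#' Simulates replicate selection experiments with a single full-penetrance
#' causal locus, maps each with the pooled engine (unselected-pool
#' subtracted) and the individual engine, and records whether a called
#' interval of superior direction contains the causal position.
#'
#' @param n_rep number of replicates.
#' @param seed root seed; replicate r uses `stage_seed(seed, "recovery", r)`.
#' @param config a [study_config()].
#' @return data.frame with logical columns `pooled_hit`, `individual_hit`,
#'   `both_hit` and numeric `pooled_width` (bp of the causal-covering pooled
#'   interval, `NA` when missed).
#' @export
recovery_study <- function(n_rep = 40, seed = 1L, config = study_config()) {
  causal <- config$causal
  res <- lapply(seq_len(n_rep), function(r) {
    cfg <- config
    cfg$seed <- stage_seed(seed, "recovery", r)
    sim <- simulate_cross(cfg, generation = "F1")
    maps <- map_simulated(sim)
    ph <- interval_containing(maps$pooled$intervals, causal$chrom[1],
                              causal$pos[1])
    ih <- interval_containing(maps$individual$intervals, causal$chrom[1],
                              causal$pos[1])
    data.frame(pooled_hit = length(ph) > 0, individual_hit = length(ih) > 0,
               both_hit = length(ph) > 0 && length(ih) > 0,
               pooled_width = if (length(ph))
                 interval_width(maps$pooled$intervals[ph[1], ]) else NA_real_)
  })
  do.call(rbind, res)
}

#' QTL-narrowing study: does inbreeding shrink the mapped interval?
#'
#' Runs paired F1 (no inbreeding) and F7 (six rounds) replicates under the
#' same phenotype and selection specification and records the width of the
#' pooled-engine interval covering the causal locus in each arm.
#'
#' @inheritParams recovery_study
#' @param rounds inbreeding rounds for the F7 arm.
#' @return data.frame with columns `rep`, `f1_width`, `f7_width` (bp, `NA`
#'   when the causal locus was missed).
#' @export
narrowing_study <- function(n_rep = 20, seed = 1L, config = study_config(),
                            rounds = 6L) {
  causal <- config$causal
  width_of <- function(sim) {
    fit <- map_pooled_qtl(sim$pool_counts, sample = "selected",
                          unselected = "unselected",
                          min_coverage = config$min_coverage,
                          min_quality = config$min_quality,
                          bandwidth = config$bandwidth,
                          alpha = config$alpha,
                          pool_size = config$k_selected)
    h <- interval_containing(fit$intervals, causal$chrom[1], causal$pos[1])
    if (length(h)) interval_width(fit$intervals[h[1], ]) else NA_real_
  }
  res <- lapply(seq_len(n_rep), function(r) {
    cfg <- config
    cfg$rounds <- rounds
    cfg$seed <- stage_seed(seed, "narrowing", r)
    f1 <- width_of(simulate_cross(cfg, generation = "F1"))
    f7 <- width_of(simulate_cross(cfg, generation = "F7"))
    data.frame(rep = r, f1_width = f1, f7_width = f7)
  })
  do.call(rbind, res)
}

#' Redundant-architecture study: can linkage shift between paralogs?
#'
#' Simulates a phenotype supported redundantly by two interchangeable loci
#' on different chromosomes and asks, per replicate, whether the individual
#' engine's averaged track (over the top `k` segregants) crosses the call
#' threshold at exactly one of the two — the signature of one causal gene
#' replacing the other in the most tolerant segregants.
#'
#' @inheritParams recovery_study
#' @param k segregants averaged by the individual engine (default 9, the
#'   most extreme tail).
#' @return data.frame with logical columns `locus_a`, `locus_b`,
#'   `exactly_one`.
#' @export
network_shift_study <- function(n_rep = 20, seed = 1L, k = 9) {
  loci <- data.frame(chrom = c("chrI", "chrIII"), pos = c(250000, 250000),
                     effect = c(1, 1))
  config <- study_config(causal = loci, architecture = "redundant",
                         groups = c(1L, 1L))
  res <- lapply(seq_len(n_rep), function(r) {
    cfg <- config
    cfg$seed <- stage_seed(seed, "netshift", r)
    sim <- simulate_cross(cfg, generation = "F1")
    maps <- map_simulated(sim, k = k)
    a <- length(interval_containing(maps$individual$intervals,
                                    loci$chrom[1], loci$pos[1])) > 0
    b <- length(interval_containing(maps$individual$intervals,
                                    loci$chrom[2], loci$pos[2])) > 0
    data.frame(locus_a = a, locus_b = b, exactly_one = xor(a, b))
  })
  do.call(rbind, res)
}

#' Null-calibration study on unselected segregants
#'
#' Simulates unselected populations (no phenotype selection), scores each
#' segregant's true genotype at every marker, applies the exact binomial
#' linkage test per marker, and also sequences an unselected pool of 27 to
#' summarise genome-wide variant frequency. Under the Mendelian null the
#' test should reject at close to its nominal level and pooled frequencies
#' should centre on 0.5.
#'
#' The design keeps the marker tests effectively independent, since the
#' naive binomial standard error of the rejection fraction is only valid
#' without linkage correlation: each replicate population contributes a
#' sparse panel of markers scattered over a 16-chromosome, 12-Mb genome
#' (neighbouring panel markers are ~100 cM apart, i.e. unlinked), and the
#' scored segregants are independent spores (one per complementary tetrad
#' pair; complete tetrads would segregate exactly 2:2 and test nothing).
#'
#' @param n_rep replicate populations.
#' @param n_seg independent segregants scored per replicate.
#' @param markers_per_rep panel size per replicate.
#' @param seed root seed.
#' @return list with `reject_rate` (fraction of marker tests with p < 0.05),
#'   `n_tests`, `median_f` (per-replicate genome-median pooled variant
#'   frequency of an unselected 27-segregant pool), `level` (the analytic
#'   rejection probability of the exact test at this `n_seg`, for
#'   reference).
#' @export
null_calibration_study <- function(n_rep = 25, n_seg = 300,
                                   markers_per_rep = 40L, seed = 1L) {
  layout <- genome_layout(stats::setNames(rep(7.5e5, 16),
                                          paste0("chr", 1:16)))
  p_sup <- founder_mosaic(layout, "superior")
  p_inf <- founder_mosaic(layout, "inferior")
  pvals <- list()
  med_f <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    s <- stage_seed(seed, "nullcal", r)
    markers <- make_parental_markers(layout, markers_per_rep, seed = s)
    set.seed(stage_seed(s, "spores"))
    pop <- vector("list", n_seg)
    i <- 0L
    while (i < n_seg) {
      tet <- meiosis(p_sup, p_inf, layout)
      take <- min(2L, n_seg - i)
      # spores 1 and 3 head the two complementary pairs and are mutually
      # independent at every locus
      pop[i + seq_len(take)] <- tet[c(1L, 3L)][seq_len(take)]
      i <- i + take
    }
    A <- allele_matrix(pop, markers)
    k <- rowSums(A == 1L)
    pvals[[r]] <- binomial_linkage_test(k, ncol(A))$p_value
    pool <- pop[sample.int(n_seg, 27L)]
    pc <- sequence_pool(pool, markers, sequencing_spec(mean_depth = 50))
    med_f[r] <- stats::median(variant_frequency(pc, 1L)$f, na.rm = TRUE)
  }
  p <- unlist(pvals)
  exact <- vapply(0:n_seg, function(k)
    stats::binom.test(k, n_seg, 0.5)$p.value, numeric(1))
  list(reject_rate = mean(p < 0.05), n_tests = length(p), median_f = med_f,
       level = sum(stats::dbinom(0:n_seg, n_seg, 0.5)[exact < 0.05]))
}
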
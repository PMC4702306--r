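## End-to-end cross/selection/sequencing simulation driver

#' Default run configuration
#'
#' One flat list holding every simulator, mapping and threshold parameter,
#' mirroring the study design it emulates: a haploid superior x inferior
#' cross, 288 F1 segregants screened with the best 27 pooled, six rounds of
#' random-spore inbreeding to an F7 population, and unselected control pools
#' of the same size.
#'
#' @param ... named overrides of any default.
#' @return a list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    chrom_lengths = c(chrI = 5e5, chrII = 5e5, chrIII = 5e5),
    cm_per_kb = 0.35,
    n_markers = 2900L,          # full-cross SNP density (~1 / 518 bp) at 1.5 Mb
    pop_size_f1 = 288L,
    pop_size_f7 = 288L,
    rounds = 6L,
    k_selected = 27L,
    causal = data.frame(chrom = "chrII", pos = 250000, effect = 1),
    architecture = "additive",
    groups = NULL,
    noise_sd = 0.1,
    baseline = 0,
    mean_depth = 50,
    depth_dispersion = 0.05,
    error_rate = 0.002,
    mean_phred = 37,
    phred_sd = 1.5,
    parent_depth = 80,
    min_coverage = 15,
    min_quality = 35,
    bandwidth = 20000,
    alpha = 0.05,
    pseudocount = 1,
    fdr_q = 0.007,
    sigma = 1000,
    window = 3000,
    call_threshold = 0.7,
    seed = 1L)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

#' Simulate a full cross/selection/sequencing experiment
#'
#' Generates parental genomes and markers, an F1 (and optionally inbred F7)
#' segregant population, polygenic phenotypes, truncation selection of the
#' top `k_selected`, an unselected control of the same size, and sequencing
#' data: pooled counts for the selected and unselected pools, individual
#' counts for the selected segregants, and parental samples. Truth (causal
#' loci and segregant mosaics) is returned for parameter-recovery checks.
#'
#' @param config a [default_config()] list.
#' @param generation `"F1"` (no inbreeding) or `"F7"` (`rounds` rounds).
#' @return a list of class `bsa_sim` with elements `layout`, `markers`,
#'   `population`, `phenotypes`, `selection`, `unselected`, `pool_counts`
#'   (samples `selected` and `unselected`), `individual_counts`,
#'   `parent_sup`, `parent_inf`, `phenotype_spec`, `config`.
#' @export
simulate_cross <- function(config = default_config(),
                           generation = c("F1", "F7")) {
  generation <- match.arg(generation)
  layout <- genome_layout(config$chrom_lengths, config$cm_per_kb)
  markers <- make_parental_markers(layout, config$n_markers, config$seed)
  p_sup <- founder_mosaic(layout, "superior")
  p_inf <- founder_mosaic(layout, "inferior")
  f0 <- cross(p_sup, p_inf)
  rounds <- if (generation == "F1") 0L else config$rounds
  pop_size <- if (generation == "F1") config$pop_size_f1 else config$pop_size_f7
  pop <- inbreed(list(f0), rounds, layout, pop_size = pop_size,
                 seed = config$seed)
  pheno_spec <- phenotype_spec(config$causal,
                               architecture = config$architecture,
                               groups = config$groups,
                               noise_sd = config$noise_sd,
                               baseline = config$baseline)
  phen <- assign_phenotypes(pop, pheno_spec, seed = config$seed)
  sel <- select_top(pop, phen, config$k_selected)
  set.seed(stage_seed(config$seed, "unselected"))
  un_idx <- sample.int(length(pop), config$k_selected)
  unsel <- structure(list(segregants = pop[un_idx],
                          phenotype = phen[un_idx], index = un_idx),
                     class = "selection")
  sq <- sequencing_spec(config$mean_depth, config$depth_dispersion,
                        config$error_rate, config$mean_phred, config$phred_sd)
  set.seed(stage_seed(config$seed, "sequencing"))
  sel_pool <- sequence_pool(sel, markers, sq, sample_name = "selected")
  un_pool <- sequence_pool(unsel, markers, sq, sample_name = "unselected")
  pool_counts <- allele_counts(markers,
                               cbind(sel_pool$sup, un_pool$sup),
                               cbind(sel_pool$inf, un_pool$inf),
                               cbind(sel_pool$qual, un_pool$qual),
                               c("selected", "unselected"))
  indiv <- sequence_segregants(sel, markers, sq)
  parent_sq <- sequencing_spec(config$parent_depth, config$depth_dispersion,
                               config$error_rate, config$mean_phred,
                               config$phred_sd)
  psup_counts <- sequence_pool(list(p_sup), markers, parent_sq,
                               sample_name = "parent_sup")
  pinf_counts <- sequence_pool(list(p_inf), markers, parent_sq,
                               sample_name = "parent_inf")
  structure(list(
    layout = layout, markers = markers, population = pop, phenotypes = phen,
    selection = sel, unselected = unsel, pool_counts = pool_counts,
    individual_counts = indiv,
    parent_sup = list(sup = as.numeric(psup_counts$sup),
                      inf = as.numeric(psup_counts$inf)),
    parent_inf = list(sup = as.numeric(pinf_counts$sup),
                      inf = as.numeric(pinf_counts$inf)),
    phenotype_spec = pheno_spec, config = config,
    generation = generation),
    class = "bsa_sim")
}

#' @export
print.bsa_sim <- function(x, ...) {
  cat("Simulated cross (", x$generation, "): ",
      length(x$population), " segregants, ",
      nrow(x$markers), " markers, top ", x$config$k_selected,
      " selected\n", sep = "")
  invisible(x)
}

#' Run both mapping engines on a simulated experiment
#'
#' Convenience driver: pooled mapping (with unselected-pool subtraction) and
#' individual mapping on the same simulated selection.
#'
#' @param sim a [simulate_cross()] result.
#' @param k segregants averaged by the individual engine (default: all
#'   selected).
#' @return list with elements `pooled` (a `pooled_qtl`) and `individual`
#'   (an `indiv_qtl`).
#' @export
map_simulated <- function(sim, k = NULL) {
  cfg <- sim$config
  pooled <- map_pooled_qtl(sim$pool_counts, sample = "selected",
                           unselected = "unselected",
                           min_coverage = cfg$min_coverage,
                           min_quality = cfg$min_quality,
                           bandwidth = cfg$bandwidth, alpha = cfg$alpha,
                           pool_size = cfg$k_selected)
  individual <- map_individual_qtl(sim$individual_counts,
                                   sim$parent_sup, sim$parent_inf,
                                   sim$layout,
                                   ranking = seq_along(sim$selection$phenotype),
                                   k = k,
                                   min_coverage = cfg$min_coverage,
                                   min_quality = cfg$min_quality,
                                   alpha = cfg$pseudocount,
                                   fdr_q = cfg$fdr_q, sigma = cfg$sigma,
                                   window = cfg$window,
                                   threshold = cfg$call_threshold)
  list(pooled = pooled, individual = individual)
}
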
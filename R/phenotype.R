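## Polygenic phenotype model and truncation selection

#' Specify a polygenic phenotype architecture
#'
#' Each causal locus contributes its effect when the segregant carries the
#' superior parent's allele there. Under the `"additive"` architecture the
#' contributions sum; under `"redundant"` the loci named in `groups`
#' contribute the maximum over group members (interchangeable causal genes,
#' as when a paralog takes over a transcription factor's role), and loci
#' outside any group remain additive.
#'
#' @param loci data.frame with columns `chrom`, `pos`, `effect` (phenotype
#'   units added when the superior allele is carried).
#' @param architecture `"additive"` or `"redundant"`.
#' @param groups integer vector of length `nrow(loci)` assigning loci to
#'   redundancy groups (`NA` = ungrouped, additive). Required when
#'   `architecture = "redundant"`.
#' @param noise_sd standard deviation of the Gaussian environmental noise.
#' @param baseline baseline phenotype value.
#' @return an object of class `phenotype_spec`.
#' @export
phenotype_spec <- function(loci, architecture = c("additive", "redundant"),
                           groups = NULL, noise_sd = 0, baseline = 0) {
  architecture <- match.arg(architecture)
  stopifnot(is.data.frame(loci),
            all(c("chrom", "pos", "effect") %in% names(loci)),
            noise_sd >= 0)
  if (architecture == "redundant") {
    if (is.null(groups) || length(groups) != nrow(loci))
      stop("redundant architecture needs one group id (or NA) per locus")
  } else {
    groups <- rep(NA_integer_, nrow(loci))
  }
  structure(list(loci = loci, architecture = architecture,
                 groups = as.integer(groups), noise_sd = noise_sd,
                 baseline = baseline),
            class = "phenotype_spec")
}

# deterministic genetic value of one segregant
genetic_value <- function(segregant, spec) {
  if (nrow(spec$loci) == 0L) return(spec$baseline)
  carries <- mosaic_alleles(segregant, spec$loci) == 1L
  contrib <- spec$loci$effect * carries
  grouped <- !is.na(spec$groups)
  value <- spec$baseline + sum(contrib[!grouped])
  if (any(grouped)) {
    for (g in unique(spec$groups[grouped])) {
      members <- which(spec$groups == g & grouped)
      value <- value + max(c(0, contrib[members]))
    }
  }
  value
}

#' Assign a phenotype score to one segregant
#'
#' @param segregant a `haplo_mosaic`.
#' @param spec a [phenotype_spec()].
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return numeric phenotype score.
#' @export
assign_phenotype <- function(segregant, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(stage_seed(seed, "phenotype"))
  genetic_value(segregant, spec) +
    if (spec$noise_sd > 0) stats::rnorm(1L, 0, spec$noise_sd) else 0
}

#' Assign phenotypes to a whole population
#'
#' @param population list of `haplo_mosaic` segregants.
#' @param spec a [phenotype_spec()].
#' @param seed integer seed for the noise draws.
#' @return numeric vector of phenotype scores, one per segregant.
#' @export
assign_phenotypes <- function(population, spec, seed = 1L) {
  set.seed(stage_seed(seed, "phenotype"))
  vapply(population, assign_phenotype, numeric(1), spec = spec)
}

#' Truncation-select the top segregants by phenotype
#'
#' @param population list of segregants.
#' @param phenotypes numeric scores, one per segregant.
#' @param k number to keep (`k <= length(population)`).
#' @return list of class `selection`: `segregants` (the k best, ranked by
#'   decreasing phenotype, ties broken by stable original order),
#'   `phenotype` (their scores) and `index` (positions in the original
#'   population).
#' @export
select_top <- function(population, phenotypes, k) {
  stopifnot(length(population) == length(phenotypes))
  if (k > length(population)) stop("k exceeds the population size")
  ord <- order(phenotypes, decreasing = TRUE)  # stable: ties keep input order
  idx <- ord[seq_len(k)]
  structure(list(segregants = population[idx],
                 phenotype = phenotypes[idx],
                 index = idx),
            class = "selection")
}
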
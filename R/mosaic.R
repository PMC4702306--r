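## Haplotype mosaics, meiosis and inbreeding

# A haplotype mosaic represents one haploid segregant genome as alternating
# parental blocks. Per chromosome: `ends` (strictly increasing block end
# positions, last equal to the chromosome length) and `labels` (+1L superior
# parent, -1L inferior parent), one label per block.

#' Construct a founder haplotype mosaic
#'
#' @param layout a [genome_layout()].
#' @param parent `"superior"` or `"inferior"`.
#' @return an object of class `haplo_mosaic`: a named per-chromosome list of
#'   `list(ends, labels)` blocks.
#' @export
founder_mosaic <- function(layout, parent = c("superior", "inferior")) {
  parent <- match.arg(parent)
  lab <- if (parent == "superior") 1L else -1L
  segs <- lapply(layout$lengths, function(L) list(ends = L, labels = lab))
  names(segs) <- layout$chrom
  structure(segs, class = "haplo_mosaic")
}

#' @export
print.haplo_mosaic <- function(x, ...) {
  nb <- sum(vapply(x, function(s) length(s$labels), 1L))
  cat("Haplotype mosaic:", length(x), "chromosome(s),", nb, "block(s)\n")
  invisible(x)
}

# merge adjacent blocks with equal labels
normalize_mosaic <- function(mosaic) {
  for (c in names(mosaic)) {
    s <- mosaic[[c]]
    if (length(s$labels) > 1L) {
      keep <- c(s$labels[-1L] != s$labels[-length(s$labels)], TRUE)
      mosaic[[c]] <- list(ends = s$ends[keep], labels = s$labels[keep])
    }
  }
  mosaic
}

#' Parental allele carried by a segregant at each marker
#'
#' @param mosaic a `haplo_mosaic`.
#' @param markers a `marker_table` (or any data.frame with `chrom` and `pos`).
#' @return integer vector, +1 where the segregant carries the superior
#'   parent's allele, -1 where the inferior parent's.
#' @export
mosaic_alleles <- function(mosaic, markers) {
  out <- integer(nrow(markers))
  for (c in unique(markers$chrom)) {
    idx <- which(markers$chrom == c)
    s <- mosaic[[c]]
    if (is.null(s)) stop("chromosome not in mosaic: ", c)
    # block i covers (ends[i-1], ends[i]]
    block <- findInterval(markers$pos[idx] - 1e-9, c(0, s$ends), left.open = FALSE)
    block <- pmin(block, length(s$labels))
    out[idx] <- s$labels[block]
  }
  out
}

#' Parental block lengths of a mosaic
#'
#' @param mosaic a `haplo_mosaic`.
#' @return numeric vector of block lengths in bp, all chromosomes pooled.
#' @export
block_lengths <- function(mosaic) {
  unlist(lapply(mosaic, function(s) diff(c(0, s$ends))), use.names = FALSE)
}

## Meiosis -------------------------------------------------------------------

# Overlay an origin pattern (which gamete segment descends from which parental
# homologue) onto the two homologue mosaics, yielding the spore's mosaic for
# one chromosome. `switches` are crossover positions at which origin flips;
# `first` is 1 (mother homologue) or 2 (father homologue) before the first
# switch.
compose_chr <- function(switches, first, mchr, fchr, L) {
  obreaks <- c(switches, L)
  ends <- numeric(0)
  labels <- integer(0)
  lo <- 0
  origin <- first
  for (hi in obreaks) {
    if (hi > lo) {
      src <- if (origin == 1L) mchr else fchr
      j <- findInterval(lo, src$ends) + 1L
      while (j <= length(src$ends) && lo < hi) {
        e <- min(src$ends[j], hi)
        ends <- c(ends, e)
        labels <- c(labels, src$labels[j])
        lo <- e
        j <- j + 1L
      }
    }
    lo <- hi
    origin <- 3L - origin
  }
  # merge adjacent equal labels
  if (length(labels) > 1L) {
    keep <- c(labels[-1L] != labels[-length(labels)], TRUE)
    ends <- ends[keep]; labels <- labels[keep]
  }
  list(ends = ends, labels = labels)
}

#' Simulate one meiosis of a diploid, returning the tetrad
#'
#' Crossovers per chromosome are drawn from a Poisson law with mean twice the
#' chromosome's map length in Morgans (one bivalent; no interference), with
#' positions uniform along the chromosome. Each of the two complementary spore
#' pairs receives each crossover independently with probability 1/2, so each
#' gamete sees Poisson(map length) crossovers and the tetrad segregates 2:2 at
#' every locus of a heterozygous diploid.
#'
#' @param mother,father the two haploid `haplo_mosaic` genomes of the diploid.
#' @param layout the shared [genome_layout()].
#' @param seed integer seed, or `NULL` to draw from the current RNG stream
#'   (used when a caller manages seeding for many meioses).
#' @return list of four `haplo_mosaic` spores; spores 1/2 and 3/4 are
#'   complementary pairs.
#' @export
meiosis <- function(mother, father, layout, seed = NULL) {
  if (!identical(names(mother), layout$chrom) ||
      !identical(names(father), layout$chrom))
    stop("mother and father must be defined on the layout's chromosomes")
  if (!is.null(seed)) set.seed(stage_seed(seed, "meiosis"))
  spores <- replicate(4, vector("list", length(layout$chrom)), simplify = FALSE)
  for (i in seq_along(layout$chrom)) {
    c <- layout$chrom[i]
    L <- layout$lengths[i]
    lm <- chrom_morgans(layout, c)
    k <- stats::rpois(1L, 2 * lm)
    xo <- sort(stats::runif(k, 0, L))
    mchr <- mother[[c]]
    fchr <- father[[c]]
    for (pair in 1:2) {
      incl <- if (k > 0) stats::runif(k) < 0.5 else logical(0)
      first <- sample(1:2, 1L)
      a <- compose_chr(xo[incl], first, mchr, fchr, L)
      b <- compose_chr(xo[incl], 3L - first, mchr, fchr, L)
      spores[[2 * pair - 1]][[i]] <- a
      spores[[2 * pair]][[i]] <- b
    }
  }
  lapply(spores, function(s) {
    names(s) <- layout$chrom
    structure(s, class = "haplo_mosaic")
  })
}

#' Cross two haploid segregants into a diploid
#'
#' @param a,b haploid `haplo_mosaic` genomes.
#' @return a list of class `diploid` with elements `a` and `b`.
#' @export
cross <- function(a, b) structure(list(a = a, b = b), class = "diploid")

# sporulate a list of diploids until `target` spores are produced, cycling
# over the diploids; each meiosis yields 4 spores
sporulate <- function(diploids, layout, target) {
  spores <- vector("list", target)
  got <- 0L
  i <- 1L
  while (got < target) {
    d <- diploids[[(i - 1L) %% length(diploids) + 1L]]
    tet <- meiosis(d$a, d$b, layout)
    take <- min(4L, target - got)
    spores[got + seq_len(take)] <- tet[seq_len(take)]
    got <- got + take
    i <- i + 1L
  }
  spores
}

#' Multi-round random-spore inbreeding of a segregant population
#'
#' Starting from one or more diploids, sporulates to a haploid population of
#' size `pop_size`, then performs `rounds` rounds of mass mating: spores are
#' paired uniformly at random (mating type abstracted away), every diploid is
#' sporulated, and the pooled spores form the next generation. `rounds = 0`
#' returns the spores of the initial cross (the F1 segregants); `rounds = 6`
#' yields an F7 population. Expected parental block length decreases with
#' rounds as recombination accumulates.
#'
#' @param diploids list of `diploid` objects (often a single F0 hybrid).
#' @param rounds number of inbreeding rounds (>= 0).
#' @param layout the [genome_layout()].
#' @param pop_size haploid population size kept each generation.
#' @param seed integer root seed for the whole inbreeding schedule.
#' @return list of `pop_size` haploid `haplo_mosaic` segregants.
#' @export
inbreed <- function(diploids, rounds, layout, pop_size = 288L, seed = 1L) {
  if (length(diploids) == 0L) stop("empty founding population")
  stopifnot(is_count(rounds), is_count(pop_size, min = 2))
  set.seed(stage_seed(seed, "inbreed"))
  spores <- sporulate(diploids, layout, pop_size)
  for (r in seq_len(rounds)) {
    idx <- sample.int(length(spores))
    n_pairs <- length(spores) %/% 2L
    dips <- lapply(seq_len(n_pairs), function(p)
      cross(spores[[idx[2 * p - 1]]], spores[[idx[2 * p]]]))
    spores <- sporulate(dips, layout, pop_size)
  }
  spores
}
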
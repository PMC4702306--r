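## Genome layout and parental marker table

#' Define a genome layout for simulation
#'
#' A layout names the chromosomes, gives their physical lengths and a single
#' genome-wide genetic map density. The default density of 0.35 cM/kb is
#' typical for *Saccharomyces cerevisiae*.
#'
#' @param lengths named numeric vector of chromosome lengths in base pairs;
#'   names are the chromosome identifiers.
#' @param cm_per_kb genetic map density in centimorgan per kilobase (>= 0).
#' @return an object of class `genome_layout` with elements `chrom`,
#'   `lengths` (named, bp) and `cm_per_kb`.
#' @examples
#' genome_layout(c(chrI = 2e5, chrII = 5e5))
#' @export
genome_layout <- function(lengths, cm_per_kb = 0.35) {
  if (is.null(names(lengths)) || anyDuplicated(names(lengths)))
    stop("chromosome lengths must have unique names")
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive")
  if (!is.numeric(cm_per_kb) || length(cm_per_kb) != 1L || cm_per_kb < 0)
    stop("cm_per_kb must be a single non-negative number")
  structure(
    list(chrom = names(lengths),
         lengths = stats::setNames(as.numeric(lengths), names(lengths)),
         cm_per_kb = as.numeric(cm_per_kb)),
    class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("Genome layout:", length(x$chrom), "chromosome(s),",
      format(sum(x$lengths), big.mark = ","), "bp,",
      x$cm_per_kb, "cM/kb\n")
  invisible(x)
}

# map length of one chromosome in Morgans
chrom_morgans <- function(layout, chrom) {
  unname(layout$lengths[chrom]) / 1000 * layout$cm_per_kb / 100
}

#' Scatter parental marker SNPs over a genome
#'
#' Places `n_markers` biallelic SNPs distinguishing the superior from the
#' inferior parent uniformly over the genome. Markers are apportioned to
#' chromosomes proportionally to physical length (largest-remainder rule) and
#' positions are drawn uniformly without replacement within each chromosome.
#'
#' @param layout a [genome_layout()].
#' @param n_markers total number of markers (>= 0).
#' @param seed integer seed; the draw is reproducible via
#'   `stage_seed(seed, "markers")`.
#' @return a `data.frame` of class `marker_table` with columns `chrom`, `pos`
#'   (1-based), `sup_allele`, `inf_allele`, sorted by (chrom, pos).
#' @examples
#' lay <- genome_layout(c(chrI = 1e4))
#' make_parental_markers(lay, 10, seed = 1)
#' @export
make_parental_markers <- function(layout, n_markers, seed) {
  stopifnot(inherits(layout, "genome_layout"), is_count(n_markers))
  if (n_markers > sum(floor(layout$lengths)))
    stop("n_markers exceeds the number of assignable positions in the genome")
  set.seed(stage_seed(seed, "markers"))
  n_chr <- marker_apportionment(layout$lengths, n_markers)
  if (any(n_chr > floor(layout$lengths)))
    stop("marker density impossible on at least one chromosome")
  rows <- lapply(seq_along(layout$chrom), function(i) {
    n <- n_chr[i]
    if (n == 0L) return(NULL)
    pos <- sort(sample.int(floor(layout$lengths[i]), n))
    data.frame(chrom = layout$chrom[i], pos = pos)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(chrom = character(), pos = integer())
  nm <- nrow(tab)
  bases <- c("A", "C", "G", "T")
  sup <- sample(bases, nm, replace = TRUE)
  shift <- sample.int(3L, nm, replace = TRUE)
  inf <- bases[(match(sup, bases) - 1L + shift) %% 4L + 1L]
  tab$sup_allele <- sup
  tab$inf_allele <- inf
  tab$chrom <- factor(tab$chrom, levels = layout$chrom)
  tab <- tab[order(tab$chrom, tab$pos), , drop = FALSE]
  tab$chrom <- as.character(tab$chrom)
  rownames(tab) <- NULL
  class(tab) <- c("marker_table", "data.frame")
  tab
}

# largest-remainder apportionment of n markers over chromosome lengths
marker_apportionment <- function(lengths, n) {
  if (n == 0L) return(integer(length(lengths)))
  quota <- n * lengths / sum(lengths)
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
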
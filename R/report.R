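## Interval reporting: widths, gene annotation, protein utilities

#' Physical width of QTL intervals
#'
#' Width is `end - start` in base pairs, the span between the two printed
#' boundary coordinates.
#'
#' @param intervals a `qtl_intervals` data.frame (or anything with `start`
#'   and `end` columns).
#' @return numeric widths in bp.
#' @export
interval_width <- function(intervals) {
  if (any(intervals$end < intervals$start)) stop("end < start")
  intervals$end - intervals$start
}

#' Width difference between two intervals
#'
#' Reports how much narrower (positive) or wider interval `b` is than `a`,
#' with kb rounding applied per interval before differencing, matching how
#' narrowing is quoted in mapping reports.
#'
#' @param a,b single-row interval data.frames.
#' @param nearest kb rounding granularity applied to each width (default 1).
#' @return width difference `a - b` in kb.
#' @export
compare_intervals <- function(a, b, nearest = 1) {
  round_kb(interval_width(a), nearest) - round_kb(interval_width(b), nearest)
}

#' Restrict intervals to their central fraction
#'
#' The gene-dense "center of the locus" reported for a mapped region is not
#' a formal object; this helper takes a configurable central fraction of
#' each interval around its midpoint (default the central half).
#'
#' @param intervals a `qtl_intervals` data.frame.
#' @param fraction central fraction in (0, 1].
#' @return the intervals with `start`/`end` shrunk.
#' @export
central_interval <- function(intervals, fraction = 0.5) {
  stopifnot(fraction > 0, fraction <= 1)
  mid <- (intervals$start + intervals$end) / 2
  half <- (intervals$end - intervals$start) * fraction / 2
  intervals$start <- floor(mid - half)
  intervals$end <- ceiling(mid + half)
  intervals
}

#' List genes overlapping QTL intervals
#'
#' A gene is reported for an interval when they share at least one base
#' (1-based inclusive coordinates on both sides). Optionally the interval is
#' first restricted to its central fraction via [central_interval()].
#'
#' @param intervals a `qtl_intervals` data.frame.
#' @param genes a [read_gene_annotation()] data.frame.
#' @param central_fraction optional fraction in (0, 1]; `NULL` uses the full
#'   interval.
#' @return list, one element per interval row, each a `gene_annotation`
#'   subset ordered by position.
#' @export
annotate_qtls <- function(intervals, genes, central_fraction = NULL) {
  if (nrow(intervals) == 0L) return(list())
  missing <- setdiff(unique(intervals$chrom), unique(genes$chrom))
  if (length(missing))
    stop("chromosomes absent from annotation: ",
         paste(missing, collapse = ", "))
  if (!is.null(central_fraction))
    intervals <- central_interval(intervals, central_fraction)
  gi <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$start, genes$end))
  qi <- GenomicRanges::GRanges(intervals$chrom,
                               IRanges::IRanges(intervals$start,
                                                intervals$end))
  hits <- GenomicRanges::findOverlaps(qi, gi)
  lapply(seq_len(nrow(intervals)), function(i) {
    g <- genes[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i], ,
               drop = FALSE]
    g[order(g$start), , drop = FALSE]
  })
}

#' Protein lengths and pairwise identity/similarity
#'
#' Residue counts (terminal stop `*` excluded) and, for each sequence pair,
#' a global (Needleman-Wunsch) alignment over the requested residue range
#' with BLOSUM62 scoring (gap opening 10, extension 0.5). Identity is the
#' fraction of aligned columns with identical residues; similarity
#' additionally counts residue pairs with a positive substitution score.
#' The scoring scheme is recorded in the output.
#'
#' @param sequences a named character vector of protein sequences, a
#'   `Biostrings::AAStringSet`, or a path to a protein FASTA file.
#' @param range optional `c(from, to)` residue range (applied to each
#'   sequence, clipped to its length) over which to align.
#' @return list with `lengths` (named residue counts) and `pairs` (a
#'   data.frame with `seq_a`, `seq_b`, `identity_pct`, `similarity_pct`,
#'   `aligned_columns`) plus `scoring` details.
#' @export
protein_stats <- function(sequences, range = NULL) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences))
    sequences <- Biostrings::readAAStringSet(sequences)
  if (!methods::is(sequences, "AAStringSet"))
    sequences <- Biostrings::AAStringSet(sequences)
  if (length(sequences) == 0L) stop("no sequences given")
  seqs <- gsub("\\*$", "", as.character(sequences))
  if (any(nchar(seqs) == 0L)) stop("empty sequence")
  lens <- stats::setNames(nchar(seqs), names(sequences))
  sub_mat <- "BLOSUM62"
  data(list = sub_mat, package = "Biostrings", envir = environment())
  mat <- get(sub_mat, envir = environment())
  pairs <- NULL
  if (length(seqs) >= 2L) {
    combs <- utils::combn(seq_along(seqs), 2L)
    rows <- apply(combs, 2L, function(ij) {
      a <- seqs[ij[1]]; b <- seqs[ij[2]]
      if (!is.null(range)) {
        a <- substr(a, range[1], min(range[2], nchar(a)))
        b <- substr(b, range[1], min(range[2], nchar(b)))
      }
      al <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                          substitutionMatrix = mat,
                                          gapOpening = 10, gapExtension = 0.5)
      pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
      pb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
      aligned <- pa != "-" & pb != "-"
      ident <- sum(pa == pb & aligned)
      simil <- sum(aligned & mapply(function(x, y) mat[x, y] > 0,
                                    pa[aligned], pb[aligned]))
      ncol_al <- length(pa)
      data.frame(seq_a = names(lens)[ij[1]], seq_b = names(lens)[ij[2]],
                 identity_pct = 100 * ident / ncol_al,
                 similarity_pct = 100 * simil / ncol_al,
                 aligned_columns = ncol_al)
    })
    pairs <- do.call(rbind, rows)
  }
  list(lengths = lens, pairs = pairs,
       scoring = list(matrix = sub_mat, gap_opening = 10,
                      gap_extension = 0.5,
                      similar = "positive substitution score"))
}
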
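## File adapters: TSV, VCF, BED/bedGraph, GFF3, YAML config

# provenance header lines ("# key=value") written atop TSV artifacts
provenance_header <- function(provenance) {
  if (is.null(provenance)) return(character(0))
  paste0("# ", names(provenance), "=", unlist(provenance))
}

#' Write / read a TSV with provenance header lines
#'
#' Generic helpers shared by every TSV artifact: `#`-prefixed `key=value`
#' header lines (seed, config hash) followed by a tab-separated table.
#'
#' @param df a data.frame.
#' @param path file path.
#' @param provenance optional named list written as header lines.
#' @return the path (write) or a data.frame (read).
#' @export
write_tsv_with_header <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(provenance), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_with_header
#' @export
read_tsv_skip_header <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write / read allele counts as TSV
#'
#' Long format, one row per marker and sample: `sample`, `chrom`, `pos`,
#' `sup_count`, `inf_count`, `mean_phred`. Optional provenance (seed, config
#' hash) is written as `#`-prefixed header lines.
#'
#' @param counts an [allele_counts()].
#' @param path output file.
#' @param provenance optional named list embedded in the header.
#' @return the path, invisibly.
#' @export
write_counts_tsv <- function(counts, path, provenance = NULL) {
  long <- do.call(rbind, lapply(seq_along(counts$samples), function(j)
    data.frame(sample = counts$samples[j],
               chrom = counts$markers$chrom, pos = counts$markers$pos,
               sup_count = counts$sup[, j], inf_count = counts$inf[, j],
               mean_phred = counts$qual[, j])))
  write_tsv_with_header(long, path, provenance)
}

#' @rdname write_counts_tsv
#' @param markers the `marker_table` the counts refer to (fixes marker order
#'   and alleles, which the counts TSV does not carry).
#' @export
read_counts_tsv <- function(path, markers) {
  long <- read_tsv_skip_header(path)
  samples <- unique(long$sample)
  key <- paste(markers$chrom, markers$pos)
  mats <- lapply(c("sup_count", "inf_count", "mean_phred"), function(col) {
    m <- sapply(samples, function(s) {
      sl <- long[long$sample == s, ]
      sl[[col]][match(key, paste(sl$chrom, sl$pos))]
    })
    matrix(m, nrow = nrow(markers))
  })
  allele_counts(markers, mats[[1]], mats[[2]], mats[[3]], samples)
}

#' Write / read the parental marker table as a minimal VCF
#'
#' VCFv4.2 with two haploid samples (`superior`, `inferior`), `GT:AD`
#' fields; REF is the superior parent's allele, ALT the inferior parent's.
#'
#' @param markers a `marker_table`.
#' @param path output `.vcf` file.
#' @param depth nominal allele depth written for each parent.
#' @return the path, invisibly.
#' @export
write_marker_vcf <- function(markers, path, depth = 50L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=bsaqtl",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "superior", "inferior", sep = "\t")), con)
  if (nrow(markers) > 0L) {
    lines <- paste(markers$chrom, markers$pos, ".", markers$sup_allele,
                   markers$inf_allele, ".", "PASS", ".", "GT:AD",
                   sprintf("0:%d,0", depth), sprintf("1:0,%d", depth),
                   sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_marker_vcf
#' @export
read_marker_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(vcfR::getFIX(v)),
                dimnames = list(NULL, colnames(vcfR::getFIX(v))))
  tab <- data.frame(chrom = as.character(fix[, "CHROM"]),
                    pos = as.integer(fix[, "POS"]),
                    sup_allele = as.character(fix[, "REF"]),
                    inf_allele = as.character(fix[, "ALT"]))
  class(tab) <- c("marker_table", "data.frame")
  tab
}

#' Export / import QTL intervals
#'
#' BED uses 0-based half-open coordinates; the TSV mirror keeps 1-based
#' inclusive coordinates as printed in genetics reports. The two describe
#' identical base sets.
#'
#' @param intervals a `qtl_intervals` data.frame.
#' @param path output file.
#' @param provenance optional named list for the TSV header.
#' @return the path, invisibly.
#' @export
write_intervals_bed <- function(intervals, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = intervals$chrom,
    ranges = IRanges::IRanges(start = intervals$start, end = intervals$end),
    name = paste0(intervals$direction, "_", seq_len(nrow(intervals))))
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname write_intervals_bed
#' @export
read_intervals_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             name = gr$name)
}

#' @rdname write_intervals_bed
#' @export
write_intervals_tsv <- function(intervals, path, provenance = NULL) {
  write_tsv_with_header(as.data.frame(intervals), path, provenance)
}

#' @rdname write_intervals_bed
#' @export
read_intervals_tsv <- function(path) {
  out <- read_tsv_skip_header(path)
  class(out) <- c("qtl_intervals", "data.frame")
  out
}

#' Write per-segregant ternary tracks as bedGraph-style TSV
#'
#' One row per window and segregant: `segregant`, `chrom`, `start0`
#' (0-based), `end` (exclusive), `call`.
#'
#' @param track a [window_calls()] result.
#' @param path output file.
#' @param provenance optional named list for the header.
#' @return the path, invisibly.
#' @export
write_track_tsv <- function(track, path, provenance = NULL) {
  rows <- list()
  for (c in names(track)) {
    t <- track[[c]]
    for (j in seq_len(ncol(t$calls)))
      rows[[length(rows) + 1L]] <- data.frame(
        segregant = j, chrom = c, start0 = t$start - 1L, end = t$end,
        call = t$calls[, j])
  }
  write_tsv_with_header(do.call(rbind, rows), path, provenance)
}

#' Read a gene annotation from GFF3
#'
#' Keeps `gene`-typed features; systematic names are taken from the `ID`
#' attribute and standard names from `Name` (falling back to the ID).
#'
#' @param path a GFF3 file.
#' @return a `data.frame` of class `gene_annotation` with columns
#'   `sys_name`, `std_name`, `chrom`, `start`, `end`, `strand`.
#' @export
read_gene_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  gr <- gr[gr$type == "gene"]
  std <- if (!is.null(gr$Name)) as.character(gr$Name) else as.character(gr$ID)
  std[is.na(std)] <- as.character(gr$ID)[is.na(std)]
  out <- data.frame(sys_name = as.character(gr$ID), std_name = std,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr),
                    end = GenomicRanges::end(gr),
                    strand = as.character(GenomicRanges::strand(gr)))
  if (anyDuplicated(out$sys_name)) stop("duplicate gene names in annotation")
  class(out) <- c("gene_annotation", "data.frame")
  out
}

## Config --------------------------------------------------------------------

#' Write / read a run configuration as YAML
#'
#' Round-trips losslessly (the causal-locus data frame is stored as a list
#' of columns).
#'
#' @param config a [default_config()] list.
#' @param path a `.yaml` file.
#' @return `write_config`: the path, invisibly; `read_config`: a
#'   `run_config` list.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$chrom_lengths <- as.list(cfg$chrom_lengths)
  cfg$causal <- as.list(cfg$causal)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$chrom_lengths <- unlist(cfg$chrom_lengths)
  cfg$causal <- as.data.frame(cfg$causal)
  do.call(default_config, cfg)
}

#' Stable hash of a run configuration
#'
#' MD5 of the canonical YAML serialisation; embedded in output-file headers
#' so every artifact records the configuration that produced it.
#'
#' @param config a `run_config` list.
#' @return character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  unname(tools::md5sum(tmp))
}
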
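## The cross-mapping read filter: before SNP calling, remove every read that
## aligns to both the plastid and the mitochondrial reference. This is the
## step that suppresses spurious "mitochondrial" variation created by
## plastid-derived insertions (MTPT) in the mitochondrial genome, where reads
## of plastid origin co-assemble with genuine mitochondrial reads.

#' Identifiers of reads mapped to both organellar genomes
#'
#' @param aln_mito,aln_plastid alignment data.frames of the same library
#'   mapped to the mitochondrial and plastid references.
#' @return character vector of read identifiers with at least one mapped
#'   record in each input. A mate counts as mapped regardless of MAPQ;
#'   mapping-quality thresholds belong to SNP calling, not to this filter.
#' @export
crossmapped_ids <- function(aln_mito, aln_plastid) {
  intersect(unique(aln_mito$qname[aln_mito$mapped]),
            unique(aln_plastid$qname[aln_plastid$mapped]))
}

#' Remove cross-mapped reads from an alignment set
#'
#' Record order is preserved and the operation is idempotent. By default
#' filtering is per read identifier (a mate that cross-maps removes only that
#' mate); `pair_mode = "pair"` removes the whole pair whenever either mate
#' cross-maps, treating identifiers as `<fragment>/1` and `<fragment>/2`.
#'
#' @param aln alignment data.frame.
#' @param crossmapped identifiers from [crossmapped_ids()].
#' @param pair_mode `"read"` (default) or `"pair"`.
#' @return the filtered alignment data.frame.
#' @export
apply_filter <- function(aln, crossmapped, pair_mode = c("read", "pair")) {
  pair_mode <- match.arg(pair_mode)
  if (pair_mode == "pair") {
    frag <- sub("/[12]$", "", aln$qname)
    drop <- frag %in% unique(sub("/[12]$", "", crossmapped))
  } else {
    drop <- aln$qname %in% crossmapped
  }
  out <- aln[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ref_lengths") <- attr(aln, "ref_lengths")
  out
}

#' Mapping and coverage statistics before/after filtering
#'
#' One row in the shape of the study's per-genome alignment summary tables:
#' read counts, mean coverage (total aligned bases / genome length, rounded
#' to integer for display) and percent of the library mapped, each before and
#' after cross-map filtering. Denominators count reads, not pairs.
#'
#' @param aln_before,aln_after alignment data.frames pre/post filter.
#' @param genome_length reference length in bp (> 0).
#' @param total_reads total reads in the library (mapped or not).
#' @param genome label for the report row.
#' @return one-row data.frame of class `filter_report`.
#' @export
filter_report <- function(aln_before, aln_after, genome_length, total_reads,
                          genome = "mito") {
  if (genome_length <= 0) stop("genome_length must be positive")
  cov <- function(aln) sum(nchar(aln$seq[aln$mapped])) / genome_length
  n_before <- sum(aln_before$mapped)
  n_after <- sum(aln_after$mapped)
  out <- data.frame(genome = genome,
                    total_reads = total_reads,
                    reads_mapped = n_before,
                    reads_mapped_after_filtering = n_after,
                    coverage = round(cov(aln_before)),
                    filtered_coverage = round(cov(aln_after)),
                    pct_mapped = 100 * n_before / total_reads,
                    pct_mapped_after_filtering = 100 * n_after / total_reads)
  class(out) <- c("filter_report", "data.frame")
  out
}
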
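## Cohort-level comparative statistics over per-cultivar SNP calls: totals,
## cultivar-unique SNPs, the shared-by-k spectrum, and the before/after
## comparison that quantifies what cross-map filtering changed. The reference
## accession contributes no records (it IS the reference); it re-enters at
## the phylogenetic stage as the reference taxon.

#' Assemble a cohort table from per-cultivar SNP records
#'
#' @param records SNP data.frame (rows from [call_snps()] or
#'   [load_paper_table()]) across cultivars of a single genome.
#' @param cultivars ordered cultivar identifiers; defaults to order of first
#'   appearance. Every record's cultivar must be listed.
#' @return object of class `cohort_table`: list with `records`, `cultivars`,
#'   `genome`.
#' @export
cohort_table <- function(records, cultivars = NULL) {
  genome <- unique(records$genome)
  if (length(genome) > 1) stop("a cohort table holds one genome at a time")
  if (length(genome) == 0) genome <- NA_character_
  if (is.null(cultivars)) cultivars <- unique(records$cultivar)
  if (!all(records$cultivar %in% cultivars)) {
    stop("records contain cultivars not listed in `cultivars`")
  }
  key <- paste(records$cultivar, records$position)
  if (anyDuplicated(key)) stop("duplicate (cultivar, position) record")
  structure(list(records = records, cultivars = cultivars, genome = genome),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("cohort_table (%s): %d records, %d cultivars, %d distinct positions\n",
              x$genome, nrow(x$records), length(x$cultivars),
              length(unique(x$records$position))))
  invisible(x)
}

#' Per-cultivar SNP counts
#'
#' @param table a [cohort_table()].
#' @return named integer vector over the table's cultivars (zeros included).
#' @export
per_cultivar_counts <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  tb <- base::table(factor(table$records$cultivar, levels = table$cultivars))
  stats::setNames(as.integer(tb), names(tb))
}

## Grouping key for sharing: a SNP is the same SNP across cultivars when it
## has the same position and the same primary alternate allele.
snp_key <- function(records) {
  paste(records$position, primary_alt(records$alt), sep = ":")
}

#' Positions unique to a single cultivar
#'
#' A position is unique to cultivar `c` when exactly one cultivar carries a
#' SNP there.
#'
#' @param table a [cohort_table()].
#' @return named list: cultivar -> integer vector of unique positions (empty
#'   vector for cultivars without unique SNPs).
#' @export
unique_snps <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  rec <- table$records
  n_by_pos <- base::table(rec$position)
  singles <- rec[rec$position %in% names(n_by_pos)[n_by_pos == 1], , drop = FALSE]
  out <- lapply(stats::setNames(table$cultivars, table$cultivars), function(cv) {
    sort(singles$position[singles$cultivar == cv])
  })
  out
}

#' Shared-by-k spectrum
#'
#' For each k, the number of distinct SNPs (same position, same primary
#' alternate) carried by exactly k cultivars.
#'
#' @param table a [cohort_table()].
#' @return named integer vector: names are k, values are SNP counts;
#'   satisfies `sum(k * spectrum[k]) == nrow(records)` when every position is
#'   biallelic.
#' @export
sharing_spectrum <- function(table) {
  stopifnot(inherits(table, "cohort_table"))
  if (nrow(table$records) == 0) return(stats::setNames(integer(0), character(0)))
  k_per_snp <- base::table(snp_key(table$records))
  tb <- base::table(as.integer(k_per_snp))
  stats::setNames(as.integer(tb), names(tb))
}

#' Compare SNP calls before and after cross-map filtering
#'
#' Classifies every (cultivar, position) seen in either call set:
#' `"filtered-out"` (called before, absent after), `"new"` (absent before),
#' `"zygosity-change"` (called in both with differing zygosity, e.g. a site
#' that lost its artifactual heteroplasmy), and `"unchanged"`.
#'
#' @param calls_before,calls_after SNP data.frames from the same library.
#' @return data.frame with `cultivar`, `position`, `status`,
#'   `zygosity_before`, `zygosity_after`; rows with status `"unchanged"` are
#'   omitted.
#' @export
compare_filtered_unfiltered <- function(calls_before, calls_after) {
  kb <- paste(calls_before$cultivar, calls_before$position)
  ka <- paste(calls_after$cultivar, calls_after$position)
  all_keys <- union(kb, ka)
  ib <- match(all_keys, kb); ia <- match(all_keys, ka)
  zb <- calls_before$zygosity[ib]; za <- calls_after$zygosity[ia]
  status <- ifelse(is.na(ia), "filtered-out",
                   ifelse(is.na(ib), "new",
                          ifelse(zb != za, "zygosity-change", "unchanged")))
  cultivar <- ifelse(is.na(ib), calls_after$cultivar[ia], calls_before$cultivar[ib])
  position <- ifelse(is.na(ib), calls_after$position[ia], calls_before$position[ib])
  out <- data.frame(cultivar = cultivar, position = position, status = status,
                    zygosity_before = zb, zygosity_after = za)
  out <- out[out$status != "unchanged", , drop = FALSE]
  rownames(out) <- NULL
  out
}
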
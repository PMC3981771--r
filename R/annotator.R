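## Genomic-context annotation of SNPs: gene (with synonymous/nonsynonymous
## effect), intron, or intergenic spacer (IGS). Overlaps resolve in the order
## coding > intron > intergenic. Labels follow the compact grammar of the
## published tables: "S-atpA", "NS-matR", "I-petD", "IGS" or "IGS-petA:psbJ".

#' Locate a position within a feature track
#'
#' @param position 1-based genomic position.
#' @param track a [feature_track()].
#' @param genome_length genome length, for bounds checking (optional).
#' @return for non-coding positions, the final label (`"I-<gene>"`, `"IGS"`
#'   or `"IGS-<left:right>"`); for coding positions the stub `"CDS-<gene>"`,
#'   refined to `"S-"`/`"NS-"` by [annotate_snps()] once the alleles are
#'   known.
#' @export
classify_location <- function(position, track, genome_length = NULL) {
  if (position < 1 || (!is.null(genome_length) && position > genome_length)) {
    stop("position outside genome")
  }
  hit <- function(type) {
    rows <- track[track$type == type &
                    track$start <= position & position <= track$end, , drop = FALSE]
    if (nrow(rows)) rows$gene[1] else NULL
  }
  g <- hit("exon")
  if (!is.null(g)) return(paste0("CDS-", g))
  g <- hit("intron")
  if (!is.null(g)) return(paste0("I-", g))
  genes <- track[track$type == "gene", , drop = FALSE]
  left <- genes[genes$end < position, , drop = FALSE]
  right <- genes[genes$start > position, , drop = FALSE]
  if (nrow(left) && nrow(right)) {
    l <- left$gene[which.max(left$end)]
    r <- right$gene[which.min(right$start)]
    paste0("IGS-", l, ":", r)
  } else {
    "IGS"
  }
}

## Concatenated coding sequence of a gene and the CDS index of a genomic
## position. Exons are joined in genomic order, then reverse-complemented for
## minus-strand genes, so cds index 1 is the first base of the start codon.
gene_cds <- function(gene, track, genome_seq) {
  ex <- track[track$type == "exon" & track$gene == gene, , drop = FALSE]
  if (nrow(ex) == 0) stop("gene has no exons in the track: ", gene)
  ex <- ex[order(ex$start), , drop = FALSE]
  parts <- substring(genome_seq, ex$start, ex$end)
  cds <- paste(parts, collapse = "")
  strand <- ex$strand[1]
  if (strand == "-") cds <- revcomp(cds)
  list(cds = cds, exons = ex, strand = strand)
}

## 1-based index of a genomic position within the (stranded) CDS.
cds_index <- function(position, cds_info) {
  ex <- cds_info$exons
  inside <- which(ex$start <= position & position <= ex$end)
  if (length(inside) == 0) stop("position not in an exon of the gene")
  before <- if (inside > 1) sum(ex$end[seq_len(inside - 1)] - ex$start[seq_len(inside - 1)] + 1L) else 0L
  fwd <- before + (position - ex$start[inside] + 1L)
  if (cds_info$strand == "+") fwd else nchar(cds_info$cds) - fwd + 1L
}

#' Synonymous or nonsynonymous effect of a coding substitution
#'
#' Translates the codon containing `position` before and after the
#' substitution, on the coding strand of `gene`. The genetic code defaults to
#' NCBI translation table 11 (bacterial/plant plastid) for both organelles.
#'
#' @param position 1-based genomic position inside an exon of `gene`.
#' @param ref_base,alt_base forward-strand alleles; `ref_base` must match the
#'   genome sequence at `position`.
#' @param gene gene identifier present in `track`.
#' @param track a [feature_track()].
#' @param genome_seq genome sequence string.
#' @param code NCBI genetic-code id passed to [Biostrings::getGeneticCode()].
#' @return `"synonymous"` or `"nonsynonymous"`.
#' @export
snp_effect <- function(position, ref_base, alt_base, gene, track, genome_seq,
                       code = "11") {
  if (substr(genome_seq, position, position) != ref_base) {
    stop("ref_base disagrees with the genome sequence at position ", position)
  }
  info <- gene_cds(gene, track, genome_seq)
  ci <- cds_index(position, info)
  ref_cds <- ref_base; alt_cds <- alt_base
  if (info$strand == "-") {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ref_cds <- comp[[ref_base]]; alt_cds <- comp[[alt_base]]
  }
  if (substr(info$cds, ci, ci) != ref_cds) {
    stop("internal CDS coordinate mismatch for gene ", gene)
  }
  codon_i <- (ci - 1L) %/% 3L
  codon <- substr(info$cds, codon_i * 3L + 1L, codon_i * 3L + 3L)
  offset <- ci - codon_i * 3L
  codon_alt <- codon
  substr(codon_alt, offset, offset) <- alt_cds
  gc <- Biostrings::getGeneticCode(code)
  if (gc[[codon]] == gc[[codon_alt]]) "synonymous" else "nonsynonymous"
}

#' Annotate SNP records with genomic-context labels
#'
#' Fills the `location` column: `"S-<gene>"`/`"NS-<gene>"` for coding
#' positions (effect from [snp_effect()]), `"I-<gene>"` for introns and an
#' IGS label otherwise.
#'
#' @param snps SNP data.frame with `position`, `ref`, `alt`.
#' @param track a [feature_track()].
#' @param genome_seq genome sequence string.
#' @param code genetic-code id (see [snp_effect()]).
#' @return `snps` with `location` filled.
#' @export
annotate_snps <- function(snps, track, genome_seq, code = "11") {
  if (nrow(snps) == 0) return(snps)
  lab <- character(nrow(snps))
  for (i in seq_len(nrow(snps))) {
    l <- classify_location(snps$position[i], track, nchar(genome_seq))
    if (startsWith(l, "CDS-")) {
      gene <- sub("^CDS-", "", l)
      eff <- snp_effect(snps$position[i], snps$ref[i], primary_alt(snps$alt[i]),
                        gene, track, genome_seq, code)
      l <- paste0(if (eff == "synonymous") "S-" else "NS-", gene)
    }
    lab[i] <- l
  }
  snps$location <- lab
  snps
}

#' Count SNP contexts (gene-S / gene-NS / intron / IGS)
#'
#' Parses location labels back into categories. The counting unit defaults to
#' distinct genome positions, the unit in which the study reports its
#' context partition; `unit = "record"` counts cultivar-by-position records.
#'
#' @param snps SNP data.frame with `position` and `location` filled.
#' @param unit `"position"` or `"record"`.
#' @return named integer vector with entries `gene_S`, `gene_NS`, `intron`,
#'   `IGS`.
#' @export
summarize_contexts <- function(snps, unit = c("position", "record")) {
  unit <- match.arg(unit)
  df <- snps
  if (unit == "position") {
    df <- df[!duplicated(df[, c("genome", "position")]), , drop = FALSE]
  }
  cat_of <- function(l) {
    if (startsWith(l, "NS-")) "gene_NS"
    else if (startsWith(l, "S-")) "gene_S"
    else if (startsWith(l, "I-")) "intron"
    else if (l == "IGS" || startsWith(l, "IGS-")) "IGS"
    else stop("unknown location label: ", l)
  }
  cats <- vapply(df$location, cat_of, "", USE.NAMES = FALSE)
  out <- c(gene_S = 0L, gene_NS = 0L, intron = 0L, IGS = 0L)
  tb <- table(cats)
  out[names(tb)] <- as.integer(tb)
  out
}
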
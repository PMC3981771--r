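## Readers/writers for the standard formats the pipeline touches, plus the
## loaders for the published SNP-table fixtures bundled under extdata/.
## FASTA/FASTQ go through Biostrings; Newick through ape. SAM is a minimal
## text dialect (11 mandatory columns, @SQ headers, ungapped CIGARs, NM tag)
## because that is exactly what the built-in mapper emits and the filter
## consumes; externally produced SAM in that dialect is accepted unchanged.

#' Read/write FASTA
#'
#' Sequences are normalised to uppercase; non-IUPAC characters are an error.
#'
#' @param path file path.
#' @return `read_fasta`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("empty FASTA: ", path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @param seqs named character vector of sequences.
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(toupper(seqs))
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read/write FASTQ (Phred+33)
#'
#' @param path file path.
#' @return `read_fastq`: data.frame with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  ss <- Biostrings::readQualityScaledDNAStringSet(path)
  data.frame(id = names(ss),
             seq = as.character(ss),
             qual = as.character(Biostrings::quality(ss)))
}

#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(reads) > 0) {
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  }
  invisible(path)
}

## Canonical empty alignment table (one row per SAM record).
empty_alignments <- function() {
  data.frame(qname = character(0), flag = integer(0), rname = character(0),
             pos = integer(0), mapq = integer(0), cigar = character(0),
             seq = character(0), qual = character(0), nm = integer(0),
             mapped = logical(0), strand = character(0))
}

#' Write alignments as SAM
#'
#' Minimal SAM 1.6 dialect: `@SQ` headers, the 11 mandatory columns and an
#' `NM:i:` tag for mapped records. Only ungapped CIGARs are produced.
#'
#' @param aln alignment data.frame (see [map_library()]).
#' @param ref_lengths named integer vector: reference name -> length.
#' @param path output path.
#' @export
write_sam <- function(aln, ref_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths), as.integer(ref_lengths)),
               "@PG\tID:orgsnp\tPN:orgsnp"), con)
  if (nrow(aln) > 0) {
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                     aln$qname, aln$flag, ifelse(aln$mapped, aln$rname, "*"),
                     ifelse(aln$mapped, aln$pos, 0L), aln$mapq,
                     ifelse(aln$mapped, aln$cigar, "*"), aln$seq, aln$qual)
    lines <- ifelse(aln$mapped, paste0(lines, "\tNM:i:", aln$nm), lines)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a SAM file (minimal dialect)
#'
#' Unmapped records (flag bit 0x4) are preserved with `mapped = FALSE`.
#' A mapped record whose RNAME is absent from the `@SQ` headers is an error.
#'
#' @param path SAM file path.
#' @return alignment data.frame with attribute `ref_lengths`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  ref_lengths <- integer(0)
  if (length(sq)) {
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    ref_lengths <- stats::setNames(ln, sn)
  }
  if (length(body) == 0) {
    out <- empty_alignments()
    attr(out, "ref_lengths") <- ref_lengths
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11)) stop("SAM record with fewer than 11 fields at line ", which(nf < 11)[1])
  field <- function(i) vapply(f, `[[`, "", i)
  flag <- as.integer(field(2))
  mapped <- bitwAnd(flag, 4L) == 0L
  rname <- field(3)
  bad <- mapped & !(rname %in% names(ref_lengths))
  if (any(bad)) stop("RNAME not declared in @SQ header: ", rname[which(bad)[1]])
  nm <- vapply(f, function(x) {
    tag <- grep("^NM:i:", x[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1])) else NA_integer_
  }, 1L)
  out <- data.frame(qname = field(1), flag = flag, rname = rname,
                    pos = as.integer(field(4)), mapq = as.integer(field(5)),
                    cigar = field(6), seq = field(10), qual = field(11),
                    nm = nm, mapped = mapped,
                    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"))
  attr(out, "ref_lengths") <- ref_lengths
  out
}

#' Load a transcribed published SNP table
#'
#' The package bundles the two cultivar-by-position SNP tables of the date
#' palm study as TSV fixtures (`table4_mito_snps.tsv`, 188 mitochondrial
#' records at 37 positions; `table5_plastid_snps.tsv`, 30 plastid records at
#' 20 positions). Bold (cultivar-unique) and asterisk (polymorphic) row
#' markers of the originals are carried as the logical columns `unique_flag`
#' and `polymorphic_flag`. A multi-allelic alternate such as "T, G" is stored
#' verbatim as `"T,G"` and counts as one record; [primary_alt()] extracts the
#' leading allele.
#'
#' @param which `"mito"` or `"plastid"`; selects the bundled fixture when
#'   `path` is `NULL`.
#' @param path optional TSV with the same columns, overriding the fixture.
#' @param validate check fixture integrity (row/site totals) on load;
#'   applied only to the bundled tables.
#' @return data.frame of SNP records with a `genome` column prepended.
#' @export
load_paper_table <- function(which = c("mito", "plastid"), path = NULL,
                             validate = TRUE) {
  which <- match.arg(which)
  bundled <- is.null(path)
  if (bundled) {
    fname <- c(mito = "table4_mito_snps.tsv", plastid = "table5_plastid_snps.tsv")[[which]]
    path <- system.file("extdata", fname, package = "orgsnp", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("cultivar", "position", "ref", "alt", "quality", "read_depth",
            "depth_ref", "depth_alt", "location", "unique_flag", "polymorphic_flag")
  if (!all(need %in% names(tab))) {
    stop("SNP table is missing columns: ", paste(setdiff(need, names(tab)), collapse = ", "))
  }
  to_int <- function(col) {
    v <- suppressWarnings(as.integer(tab[[col]]))
    bad <- which(is.na(v) & nzchar(tab[[col]]))
    if (length(bad)) stop("malformed ", col, " field at line ", bad[1] + 1L, " of ", path)
    v
  }
  out <- data.frame(cultivar = tab$cultivar, genome = which,
                    position = to_int("position"), ref = tab$ref,
                    alt = gsub("[ ]", "", tab$alt),
                    quality = as.numeric(tab$quality),
                    read_depth = to_int("read_depth"),
                    depth_ref = to_int("depth_ref"),
                    depth_alt = to_int("depth_alt"),
                    location = tab$location,
                    unique_flag = as.logical(tab$unique_flag),
                    polymorphic_flag = as.logical(tab$polymorphic_flag))
  if (any(out$depth_ref + out$depth_alt > out$read_depth)) {
    stop("depth_ref + depth_alt exceeds read_depth in ", path)
  }
  pref <- sub("-.*$", "", out$location)
  if (!all(pref %in% c("IGS", "I", "S", "NS"))) {
    stop("unknown location label prefix in ", path)
  }
  if (bundled && validate) {
    n_sites <- length(unique(out$position))
    expect <- if (which == "mito") c(188L, 37L) else c(30L, 20L)
    if (nrow(out) != expect[1] || n_sites != expect[2]) {
      stop(sprintf("fixture integrity check failed for %s table: %d rows / %d sites",
                   which, nrow(out), n_sites))
    }
  }
  out
}

#' Primary alternate allele of possibly multi-allelic records
#'
#' @param alt character vector like `"T"` or `"T,G"`.
#' @return the first-listed allele.
#' @export
primary_alt <- function(alt) sub(",.*$", "", alt)

#' Write SNP records as VCF 4.2
#'
#' One reference per file; QUAL holds the variant quality and INFO carries
#' `DP` (total read depth), `DPR` (reads supporting the reference) and `DPA`
#' (reads supporting the alternate). Multi-allelic alternates are emitted
#' comma-separated in ALT.
#'
#' @param snps SNP data.frame (columns `position`, `ref`, `alt`, `quality`,
#'   `read_depth`, `depth_ref`, `depth_alt`).
#' @param reference_name CHROM value, e.g. `"chrM"`.
#' @param path output path.
#' @export
write_vcf <- function(snps, reference_name, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##reference=%s", reference_name),
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
               "##INFO=<ID=DPR,Number=1,Type=Integer,Description=\"Reads supporting reference\">",
               "##INFO=<ID=DPA,Number=1,Type=Integer,Description=\"Reads supporting alternate\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(snps) > 0) {
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%s\tPASS\tDP=%d;DPR=%d;DPA=%d",
                       reference_name, snps$position, snps$ref,
                       gsub(" ", "", snps$alt),
                       format(snps$quality, trim = TRUE),
                       snps$read_depth, snps$depth_ref, snps$depth_alt), con)
  }
  invisible(path)
}

#' Read/write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] and [ape::write.tree()] so all tree
#' serialisation goes through one interface.
#'
#' @param path file path.
#' @return `read_newick`: an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick in ", path)
  tr
}

#' @param tree a `phylo` object.
#' @rdname read_newick
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Build or read a feature track
#'
#' A feature track is the flat gene/exon/intron annotation the SNP annotator
#' consumes: 1-based inclusive coordinates, `strand` in `+`/`-`, and a `gene`
#' column tying exons and introns to their parent gene.
#'
#' @param df data.frame with columns `feature_id`, `type` (gene/exon/intron),
#'   `start`, `end`, `strand`, `gene`.
#' @return validated feature track data.frame (class `feature_track`).
#' @export
feature_track <- function(df) {
  need <- c("feature_id", "type", "start", "end", "strand", "gene")
  stopifnot(all(need %in% names(df)))
  if (!all(df$type %in% c("gene", "exon", "intron"))) {
    stop("feature type must be gene, exon or intron")
  }
  if (any(df$start > df$end)) stop("feature with start > end")
  if (!all(df$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  class(df) <- c("feature_track", "data.frame")
  df
}

#' @param path GFF3 file (requires the rtracklayer package); `gene`,
#'   `exon` and `intron` features are kept, others ignored.
#' @rdname feature_track
#' @export
read_gff <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_gff() requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df <- df[df$type %in% c("gene", "exon", "intron"), , drop = FALSE]
  id <- if ("ID" %in% names(df)) df$ID else df$Name
  gene <- if ("Parent" %in% names(df)) {
    p <- vapply(df$Parent, function(x) if (length(x)) as.character(x[1]) else NA_character_, "")
    ifelse(is.na(p) | !nzchar(p), id, p)
  } else id
  feature_track(data.frame(feature_id = as.character(id),
                           type = as.character(df$type),
                           start = df$start, end = df$end,
                           strand = as.character(df$strand),
                           gene = as.character(gene)))
}
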
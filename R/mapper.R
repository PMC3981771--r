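## Minimal seed-and-verify read aligner: exact k-mer seeds anchor candidate
## placements which are verified by full-length Hamming comparison on both
## strands. Ungapped by design -- the simulator plants substitutions only and
## the downstream analysis concerns SNPs. Externally produced SAM in the
## package dialect can be substituted at the same interface.

#' Build a k-mer seed index over a reference sequence
#'
#' @param reference reference sequence (ACGT string).
#' @param k seed length (default 15 tolerates ~2% divergence plus sequencing
#'   error on 100 bp reads).
#' @return object of class `seed_index` holding every k-mer's 1-based
#'   occurrence positions.
#' @export
build_index <- function(reference, k = 15L) {
  stopifnot(k >= 1)
  len <- nchar(reference)
  if (k > len) stop("k exceeds reference length")
  n <- len - k + 1L
  kmers <- substring(reference, seq_len(n), seq_len(n) + k - 1L)
  env <- list2env(split(seq_len(n), kmers), hash = TRUE)
  structure(list(k = as.integer(k), env = env,
                 ref_int = seq_to_int(reference), ref_len = len),
            class = "seed_index")
}

## Positions at which a k-mer occurs (integer(0) if absent).
index_lookup <- function(index, kmer) {
  index$env[[kmer]] %||% integer(0)
}

## Disjoint seed windows tiling the read, plus the final k-mer. With at
## least max_mismatch + 1 disjoint seeds, any placement within the mismatch
## budget leaves one seed untouched (pigeonhole), so seed-and-extend finds
## exactly the placements an exhaustive Hamming scan would.
seed_offsets <- function(read_len, k) {
  unique(c(seq.int(1L, read_len - k + 1L, by = k), read_len - k + 1L))
}

#' Map a single read against an indexed reference
#'
#' Candidate placements are k-mer seed hits (both strands) extended by
#' full-length Hamming comparison; the best placement is the one with fewest
#' mismatches. Seeds tile the read in disjoint windows, so whenever the read
#' is long enough to hold `max_mismatch + 1` of them (100 bp at the
#' defaults), every placement within the mismatch budget is guaranteed to be
#' examined and the search is equivalent to an exhaustive scan. Mapping quality is 0 when two or more placements tie at the
#' best mismatch count, otherwise `min(60, 20 * (second_best - best))` with
#' `second_best = max_mismatch + 1` when no second candidate exists. Reads
#' whose best placement exceeds `max_mismatch` are returned unmapped.
#'
#' @param read read sequence (ACGT string, length >= k).
#' @param index a `seed_index` from [build_index()].
#' @param max_mismatch maximum Hamming distance for a valid placement.
#' @return list with `mapped`, `pos` (1-based leftmost), `strand`,
#'   `mismatches`, `mapq`.
#' @export
map_read <- function(read, index, max_mismatch = 5L) {
  L <- nchar(read)
  if (L < index$k) stop("read shorter than seed length")
  fwd <- seq_to_int(read)
  rev <- seq_to_int(revcomp(read))
  offs <- seed_offsets(L, index$k)
  map_read_int(fwd, rev, read, revcomp(read), offs, index, max_mismatch)
}

## Core placement search on integer-encoded read (fwd and revcomp forms).
map_read_int <- function(fwd, rev, fwd_str, rev_str, offs, index, max_mismatch) {
  L <- length(fwd)
  k <- index$k
  ref <- index$ref_int
  ref_len <- index$ref_len
  cand_pos <- integer(0)
  cand_strand <- character(0)
  for (strand in c("+", "-")) {
    s <- if (strand == "+") fwd_str else rev_str
    hits <- integer(0)
    for (o in offs) {
      hits <- c(hits, index_lookup(index, substr(s, o, o + k - 1L)) - (o - 1L))
    }
    hits <- unique(hits)
    hits <- hits[hits >= 1L & hits + L - 1L <= ref_len]
    cand_pos <- c(cand_pos, hits)
    cand_strand <- c(cand_strand, rep(strand, length(hits)))
  }
  if (length(cand_pos) == 0) {
    return(list(mapped = FALSE, pos = NA_integer_, strand = NA_character_,
                mismatches = NA_integer_, mapq = 0L))
  }
  mm <- integer(length(cand_pos))
  for (i in seq_along(cand_pos)) {
    v <- if (cand_strand[i] == "+") fwd else rev
    mm[i] <- sum(ref[cand_pos[i]:(cand_pos[i] + L - 1L)] != v)
  }
  o <- order(mm, cand_pos)
  best <- mm[o[1]]
  if (best > max_mismatch) {
    return(list(mapped = FALSE, pos = NA_integer_, strand = NA_character_,
                mismatches = NA_integer_, mapq = 0L))
  }
  tie <- sum(mm == best) >= 2L
  second <- if (length(mm) >= 2L) mm[o[2]] else max_mismatch + 1L
  mapq <- if (tie) 0L else min(60L, 20L * (min(second, max_mismatch + 1L) - best))
  list(mapped = TRUE, pos = cand_pos[o[1]], strand = cand_strand[o[1]],
       mismatches = best, mapq = as.integer(mapq))
}

#' Map a paired-end library against one reference
#'
#' Each mate is mapped independently with [map_read()]; pairing information is
#' not used to rescue placements. For records on the reverse strand the
#' stored SEQ/QUAL are reverse-complemented/reversed so that SEQ always reads
#' along the reference forward strand, as in SAM.
#'
#' @param reads1,reads2 data.frames with `id`, `seq`, `qual` (mates in the
#'   same order; `reads2` may be `NULL` for a single-end library).
#' @param reference reference sequence string.
#' @param ref_name reference name used in RNAME.
#' @param k seed length.
#' @param max_mismatch maximum Hamming distance.
#' @return alignment data.frame (one row per mate) with attribute
#'   `ref_lengths`, suitable for [write_sam()] and [pileup()].
#' @export
map_library <- function(reads1, reads2 = NULL, reference, ref_name = "ref",
                        k = 15L, max_mismatch = 5L) {
  if (!is.null(reads2) && nrow(reads1) != nrow(reads2)) {
    stop("mate count mismatch between reads1 and reads2")
  }
  reads <- rbind(reads1, reads2)
  index <- build_index(reference, k)
  n <- nrow(reads)
  out <- empty_alignments()
  if (n > 0) {
    seqs <- reads$seq
    rcs <- revcomp(seqs)
    pos <- integer(n); mapq <- integer(n); mm <- integer(n)
    mapped <- logical(n); strand <- character(n)
    for (i in seq_len(n)) {
      r <- map_read_int(seq_to_int(seqs[i]), seq_to_int(rcs[i]),
                        seqs[i], rcs[i],
                        seed_offsets(nchar(seqs[i]), k), index, max_mismatch)
      mapped[i] <- r$mapped
      pos[i] <- if (r$mapped) r$pos else 0L
      strand[i] <- if (r$mapped) r$strand else "+"
      mm[i] <- if (r$mapped) r$mismatches else NA_integer_
      mapq[i] <- r$mapq
    }
    flag <- ifelse(mapped, ifelse(strand == "-", 16L, 0L), 4L)
    seq_out <- ifelse(mapped & strand == "-", rcs, seqs)
    qual_out <- ifelse(mapped & strand == "-", reverse_strings(reads$qual), reads$qual)
    out <- data.frame(qname = reads$id, flag = flag, rname = ref_name,
                      pos = pos, mapq = mapq,
                      cigar = paste0(nchar(seqs), "M"),
                      seq = seq_out, qual = qual_out, nm = mm,
                      mapped = mapped, strand = strand)
  }
  attr(out, "ref_lengths") <- stats::setNames(nchar(reference), ref_name)
  out
}

## Reverse each string of a character vector.
reverse_strings <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE)
}
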
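## Pileup construction and threshold-based SNP calling. The retention rule is
## the study's: read depth >= 10, mapping quality >= 20 (gating reads as they
## enter the pileup) and SNP quality >= 15. Variant quality is a defined
## binomial-tail score: the phred-scaled probability of seeing at least the
## observed alternate count from sequencing error alone.

#' SNP retention thresholds
#'
#' Defaults are the study's retention rule (depth 10 / MAPQ 20 / quality 15).
#'
#' @param min_depth minimum total read depth at the site.
#' @param min_mapq minimum read mapping quality to enter the pileup.
#' @param min_snp_quality minimum phred-scaled variant quality.
#' @return list of class `call_thresholds`.
#' @export
call_thresholds <- function(min_depth = 10L, min_mapq = 20L, min_snp_quality = 15) {
  stopifnot(min_depth >= 0, min_mapq >= 0, min_snp_quality >= 0)
  structure(list(min_depth = min_depth, min_mapq = min_mapq,
                 min_snp_quality = min_snp_quality),
            class = "call_thresholds")
}

#' Per-position base counts from ungapped alignments
#'
#' Each mapped base of each retained read contributes to exactly one column.
#' Reads with MAPQ below `min_mapq` are excluded here, so the mapping-quality
#' threshold of the retention rule is applied at pileup time. Only ungapped
#' CIGARs (`<n>M`) are accepted; an alignment extending past the reference
#' end is an error.
#'
#' @param aln alignment data.frame.
#' @param reference reference sequence string.
#' @param min_mapq mapping-quality gate (default from [call_thresholds()]).
#' @return data.frame with one row per reference position: `position`,
#'   `ref_base`, counts `A`,`C`,`G`,`T`, `depth`, `mean_mapq`, `mean_baseq`.
#' @export
pileup <- function(aln, reference, min_mapq = 20L) {
  ref_len <- nchar(reference)
  keep <- aln$mapped & aln$mapq >= min_mapq
  aln <- aln[keep, , drop = FALSE]
  counts <- matrix(0L, nrow = ref_len, ncol = 4L,
                   dimnames = list(NULL, DNA_BASES))
  qsum <- numeric(ref_len); msum <- numeric(ref_len); depth <- integer(ref_len)
  if (nrow(aln) > 0) {
    lens <- nchar(aln$seq)
    if (!all(aln$cigar == paste0(lens, "M"))) {
      stop("pileup() accepts only ungapped full-length CIGARs")
    }
    if (any(aln$pos + lens - 1L > ref_len)) {
      stop("alignment extends past the reference end")
    }
    positions <- unlist(Map(function(p, l) p:(p + l - 1L), aln$pos, lens),
                        use.names = FALSE)
    bases <- base_to_int(unlist(strsplit(aln$seq, "", fixed = TRUE), use.names = FALSE))
    quals <- unlist(lapply(aln$qual, utf8ToInt), use.names = FALSE) - 33L
    mapqs <- rep(aln$mapq, lens)
    tab <- tabulate((positions - 1L) * 4L + bases, nbins = 4L * ref_len)
    counts[] <- matrix(tab, nrow = ref_len, byrow = TRUE)
    depth <- as.integer(rowSums(counts))
    qs <- rowsum(quals, positions)
    ms <- rowsum(mapqs, positions)
    qsum[as.integer(rownames(qs))] <- qs[, 1]
    msum[as.integer(rownames(ms))] <- ms[, 1]
  }
  data.frame(position = seq_len(ref_len),
             ref_base = strsplit(reference, "", fixed = TRUE)[[1]],
             counts,
             depth = depth,
             mean_mapq = ifelse(depth > 0, msum / depth, 0),
             mean_baseq = ifelse(depth > 0, qsum / depth, 0))
}

#' Phred-scaled binomial-tail variant quality
#'
#' With per-base error probability `e = 10^(-mean_baseq/10)` and `k` reads
#' supporting the top non-reference base out of `depth`, the score is
#' `min(99, -10*log10 P(X >= k))` for `X ~ Binomial(depth, e)`; zero when
#' `k = 0`. It answers: how surprising is this much alternate evidence under
#' sequencing error alone?
#'
#' @param depth total read depth (vectorised).
#' @param alt_count reads supporting the candidate alternate.
#' @param mean_baseq mean base quality at the site.
#' @return numeric vector of phred-scaled scores in `[0, 99]`.
#' @export
variant_quality <- function(depth, alt_count, mean_baseq) {
  stopifnot(all(depth >= 1), all(alt_count >= 0), all(alt_count <= depth))
  e <- 10^(-mean_baseq / 10)
  lp <- stats::pbinom(alt_count - 1L, depth, e, lower.tail = FALSE, log.p = TRUE)
  score <- pmin(99, -10 * lp / log(10))
  ifelse(alt_count == 0L, 0, score)
}

#' Call SNPs from a pileup under retention thresholds
#'
#' A site is called when its depth reaches `min_depth`, at least one
#' non-reference base is observed, and the binomial-tail variant quality of
#' the most frequent non-reference base reaches `min_snp_quality`. Ties
#' between alternate bases are broken alphabetically and flagged; a second
#' non-reference base with appreciable support (>= 2 reads and >= 10% of the
#' site depth) is recorded in `secondary_alt`, so multi-allelic sites yield
#' one record. Reads carrying bases other than the reference or the chosen
#' alternate count toward `read_depth` but toward neither depth field.
#'
#' @param pile pileup data.frame from [pileup()].
#' @param thresholds a [call_thresholds()] object.
#' @param cultivar,genome labels copied onto each record.
#' @return SNP data.frame: `cultivar`, `genome`, `position`, `ref`, `alt`,
#'   `quality`, `read_depth`, `depth_ref`, `depth_alt`, `zygosity`,
#'   `secondary_alt`, `alt_tie`, `location` (NA; see [annotate_snps()]).
#' @export
call_snps <- function(pile, thresholds = call_thresholds(),
                      cultivar = "sample", genome = "mito") {
  stopifnot(inherits(thresholds, "call_thresholds"))
  cm <- as.matrix(pile[, DNA_BASES])
  ref_idx <- match(pile$ref_base, DNA_BASES)
  alt_cm <- cm
  alt_cm[cbind(seq_len(nrow(cm)), ref_idx)] <- -1L
  alt_idx <- max.col(alt_cm, ties.method = "first")
  alt_count <- alt_cm[cbind(seq_len(nrow(cm)), alt_idx)]
  cand <- which(pile$depth >= thresholds$min_depth & alt_count > 0)
  if (length(cand) == 0) return(empty_snps())
  qual <- variant_quality(pile$depth[cand], alt_count[cand], pile$mean_baseq[cand])
  keep <- qual >= thresholds$min_snp_quality
  cand <- cand[keep]; qual <- qual[keep]
  if (length(cand) == 0) return(empty_snps())

  alt_tie <- logical(length(cand))
  secondary <- rep(NA_character_, length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    nonref <- alt_cm[i, ]
    top <- alt_count[i]
    alt_tie[j] <- sum(nonref == top) >= 2L
    second <- order(nonref, decreasing = TRUE)[2]
    if (nonref[second] >= 2L && nonref[second] >= 0.1 * pile$depth[i]) {
      secondary[j] <- DNA_BASES[second]
    }
  }
  ref_count <- cm[cbind(cand, ref_idx[cand])]
  out <- data.frame(cultivar = cultivar, genome = genome,
                    position = pile$position[cand],
                    ref = pile$ref_base[cand],
                    alt = DNA_BASES[alt_idx[cand]],
                    quality = round(qual, 1),
                    read_depth = pile$depth[cand],
                    depth_ref = as.integer(ref_count),
                    depth_alt = as.integer(alt_count[cand]),
                    zygosity = classify_zygosity(ref_count, alt_count[cand]),
                    secondary_alt = secondary,
                    alt_tie = alt_tie,
                    location = NA_character_)
  rownames(out) <- NULL
  out
}

empty_snps <- function() {
  data.frame(cultivar = character(0), genome = character(0),
             position = integer(0), ref = character(0), alt = character(0),
             quality = numeric(0), read_depth = integer(0),
             depth_ref = integer(0), depth_alt = integer(0),
             zygosity = character(0), secondary_alt = character(0),
             alt_tie = logical(0), location = character(0))
}

#' Homoplasmic versus heteroplasmic classification
#'
#' A SNP is heteroplasmic exactly when reads supporting the reference AND
#' reads supporting the alternate are both present; with zero
#' reference-supporting reads it is homoplasmic. This is the only rule
#' consistent with the published per-SNP depth tables, where polymorphic
#' (asterisked) rows are precisely those with both depths positive.
#'
#' @param depth_ref,depth_alt reads supporting reference/alternate
#'   (vectorised). `depth_alt` must be positive: a site without alternate
#'   support is not a SNP.
#' @return character vector, `"homoplasmic"` or `"heteroplasmic"`.
#' @export
classify_zygosity <- function(depth_ref, depth_alt) {
  if (any(depth_alt == 0)) stop("depth_alt must be positive: not a SNP")
  ifelse(depth_ref > 0, "heteroplasmic", "homoplasmic")
}
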
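## Synthetic organellar data: miniature reference genomes with
## plastid-to-mitochondrion DNA transfers (MTPT), cultivar variant profiles
## including heteroplasmy, and paired-end reads with a ground-truth sidecar.
## Everything downstream of sequencing is testable against these truths.

#' Simulate a plastid/mitochondrion/nuclear reference trio with MTPT segments
#'
#' Generates three random genomes and plants `n_segments` plastid-derived
#' segments into the mitochondrial genome so that the planted fraction of the
#' mitochondrial genome approximates `transfer_fraction`. Date palm motivates
#' the defaults: roughly a tenth of the real mitochondrial genome is
#' plastid-derived insertion, which is what makes naive organellar SNP calling
#' produce spurious heteroplasmy. The mitochondrial copy of each segment is
#' diverged from its plastid source by independent per-site substitutions at
#' rate `divergence`; the plastid source is left untouched (transfer is
#' modelled plastid -> mitochondrion only).
#'
#' @param plastid_len,mito_len,nuclear_len genome lengths in bp (>= 1000).
#' @param transfer_fraction target fraction of the mitochondrial genome made
#'   of plastid insertions, in `[0, 1)`.
#' @param n_segments number of transfer segments (near-equal lengths).
#' @param divergence per-site substitution probability applied to the
#'   mitochondrial copy of each segment.
#' @param seed integer seed; output is fully determined by it.
#' @return an object of class `reference_pair`: list with `plastid_seq`,
#'   `mito_seq`, `nuclear_seq` (uppercase ACGT strings) and `transfers`, a
#'   data.frame with 1-based inclusive columns `mito_start`, `mito_end`,
#'   `plastid_start`, `plastid_end` and `divergence`. Segments are mutually
#'   non-overlapping on both genomes.
#' @export
simulate_references <- function(plastid_len = 20000L, mito_len = 50000L,
                                nuclear_len = 100000L,
                                transfer_fraction = 0.103, n_segments = 5L,
                                divergence = 0.02, seed = 1L) {
  stopifnot(plastid_len >= 1000, mito_len >= 1000, nuclear_len >= 1000,
            transfer_fraction >= 0, transfer_fraction < 1,
            n_segments >= 0, divergence >= 0, divergence <= 1)
  total <- round(transfer_fraction * mito_len)
  if (total > plastid_len) {
    stop("transfer_fraction * mito_len exceeds plastid_len: cannot source segments")
  }
  set.seed(seed)
  plastid <- seq_to_int(random_dna(plastid_len))
  mito <- seq_to_int(random_dna(mito_len))
  nuclear <- random_dna(nuclear_len)

  transfers <- data.frame(mito_start = integer(0), mito_end = integer(0),
                          plastid_start = integer(0), plastid_end = integer(0),
                          divergence = numeric(0))
  if (n_segments > 0 && total > 0) {
    lens <- rep(total %/% n_segments, n_segments)
    extra <- total - sum(lens)
    if (extra > 0) lens[seq_len(extra)] <- lens[seq_len(extra)] + 1L
    lens <- lens[lens > 0]
    src <- sample_disjoint_intervals(plastid_len, lens)
    dst <- sample_disjoint_intervals(mito_len, lens)
    for (i in seq_along(lens)) {
      seg <- plastid[src[i]:(src[i] + lens[i] - 1L)]
      idx <- which(stats::runif(lens[i]) < divergence)
      mito[dst[i]:(dst[i] + lens[i] - 1L)] <- mutate_bases(seg, idx)
    }
    transfers <- data.frame(mito_start = dst, mito_end = dst + lens - 1L,
                            plastid_start = src, plastid_end = src + lens - 1L,
                            divergence = divergence)
    transfers <- transfers[order(transfers$mito_start), , drop = FALSE]
    rownames(transfers) <- NULL
  }
  structure(list(plastid_seq = int_to_seq(plastid),
                 mito_seq = int_to_seq(mito),
                 nuclear_seq = nuclear,
                 transfers = transfers,
                 seed = seed),
            class = "reference_pair")
}

## Rejection-sample starts of disjoint intervals of the given lengths on
## 1..genome_len. Deterministic under the caller's RNG state.
sample_disjoint_intervals <- function(genome_len, lens) {
  starts <- integer(0)
  ends <- integer(0)
  for (len in lens) {
    placed <- FALSE
    for (try in 1:10000) {
      s <- sample.int(genome_len - len + 1L, 1L)
      e <- s + len - 1L
      if (!any(s <= ends & e >= starts)) {
        starts <- c(starts, s); ends <- c(ends, e)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place disjoint transfer segments; reduce transfer_fraction")
  }
  starts
}

#' @export
print.reference_pair <- function(x, ...) {
  cat(sprintf("reference_pair: plastid %d bp, mito %d bp, nuclear %d bp; %d transfer segment(s) (%.1f%% of mito)\n",
              nchar(x$plastid_seq), nchar(x$mito_seq), nchar(x$nuclear_seq),
              nrow(x$transfers),
              100 * sum(x$transfers$mito_end - x$transfers$mito_start + 1) / nchar(x$mito_seq)))
  invisible(x)
}

## Positions of a genome lying inside (or outside) the transfer segments.
transfer_positions <- function(refs, genome = c("mito", "plastid")) {
  genome <- match.arg(genome)
  tr <- refs$transfers
  if (nrow(tr) == 0) return(integer(0))
  if (genome == "mito") {
    unlist(Map(seq.int, tr$mito_start, tr$mito_end), use.names = FALSE)
  } else {
    unlist(Map(seq.int, tr$plastid_start, tr$plastid_end), use.names = FALSE)
  }
}

#' Simulate a cultivar's organellar variant profile
#'
#' Draws the requested numbers of substitution variants on the mitochondrial
#' and plastid genomes. A `het_fraction` share of variants is heteroplasmic,
#' with allele fraction drawn uniformly from `af_range`; the remainder are
#' homoplasmic (allele fraction 1). By default positions inside transfer
#' segments (and their plastid sources) are avoided, so that planted variants
#' are unambiguously attributable to one genome.
#'
#' @param refs a `reference_pair`.
#' @param name cultivar identifier.
#' @param n_mito_snps,n_plastid_snps number of variants per genome.
#' @param het_fraction fraction of variants made heteroplasmic, in `[0, 1]`.
#' @param af_range length-2 numeric in `(0, 1]`: uniform range for
#'   heteroplasmic allele fractions.
#' @param avoid_transfers logical; keep variants out of transfer segments.
#' @param seed integer seed.
#' @return object of class `cultivar_profile`: list with `name` and
#'   `variants`, a data.frame with columns `genome` ("mito"/"plastid"),
#'   `position` (1-based), `ref_base`, `alt_base`, `allele_fraction`.
#' @export
simulate_cultivar <- function(refs, name = "CV1", n_mito_snps = 10L,
                              n_plastid_snps = 5L, het_fraction = 0,
                              af_range = c(0.2, 0.8), avoid_transfers = TRUE,
                              seed = 1L) {
  stopifnot(inherits(refs, "reference_pair"),
            n_mito_snps >= 0, n_plastid_snps >= 0,
            het_fraction >= 0, het_fraction <= 1, length(af_range) == 2)
  if (af_range[1] <= 0 || af_range[2] > 1 || af_range[1] > af_range[2]) {
    stop("af_range must lie in (0, 1] with af_range[1] <= af_range[2]")
  }
  set.seed(seed)
  draw <- function(genome, seq, n) {
    if (n == 0) {
      return(data.frame(genome = character(0), position = integer(0),
                        ref_base = character(0), alt_base = character(0),
                        allele_fraction = numeric(0)))
    }
    len <- nchar(seq)
    allowed <- seq_len(len)
    if (avoid_transfers) {
      allowed <- setdiff(allowed, transfer_positions(refs, genome))
    }
    if (n > length(allowed)) stop("more variants requested than available positions")
    pos <- sort(sample(allowed, n))
    iseq <- seq_to_int(seq)
    ref <- DNA_BASES[iseq[pos]]
    alt <- DNA_BASES[mutate_bases(iseq[pos], seq_len(n))]
    af <- rep(1, n)
    n_het <- round(het_fraction * n)
    if (n_het > 0) {
      het_idx <- sample.int(n, n_het)
      af[het_idx] <- stats::runif(n_het, af_range[1], af_range[2])
    }
    data.frame(genome = genome, position = pos, ref_base = ref,
               alt_base = alt, allele_fraction = af)
  }
  variants <- rbind(draw("mito", refs$mito_seq, n_mito_snps),
                    draw("plastid", refs$plastid_seq, n_plastid_snps))
  rownames(variants) <- NULL
  structure(list(name = name, variants = variants), class = "cultivar_profile")
}

#' Simulate paired-end reads from a cultivar's organellar + nuclear DNA
#'
#' Fragments are sampled uniformly from each linear genome with
#' normally-distributed insert sizes; 100 bp mates are taken from the fragment
#' ends (mate 2 reverse-complemented). Expected per-genome depth equals
#' `base_coverage * copy_numbers[genome]`, emulating the copy-number ladder of
#' total-DNA sequencing (plastid >> mitochondrion >> nucleus). Heteroplasmic
#' variants are assigned per fragment with probability equal to their allele
#' fraction, so both mates of a fragment carry the same allele. Sequencing
#' errors are i.i.d. substitutions at `error_rate`; the constant base-quality
#' string encodes `round(-10*log10(error_rate))` capped at 40.
#'
#' @param refs a `reference_pair`.
#' @param profile a `cultivar_profile` (variants to plant on the reads).
#' @param copy_numbers named numeric vector with entries `plastid`, `mito`,
#'   `nuclear`: per-genome depth multipliers.
#' @param base_coverage depth of a copy-number-1 genome.
#' @param read_len read length (bp); must be below `insert_mean`.
#' @param insert_mean,insert_sd fragment length distribution.
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed; byte-identical output for identical inputs.
#' @return list with `reads1` and `reads2` (data.frames `id`, `seq`, `qual`;
#'   ids carry `/1` and `/2` mate suffixes) and `truth`, one row per mate:
#'   `read_id`, `genome`, `start` (1-based leftmost position of the mate on
#'   its genome), `strand`, `mate`, `insert`, and `variants` ("pos:alt"
#'   entries carried by that mate, comma-separated).
#' @export
simulate_reads <- function(refs, profile,
                           copy_numbers = c(plastid = 4, mito = 1, nuclear = 0.02),
                           base_coverage = 100, read_len = 100L,
                           insert_mean = 300, insert_sd = 30,
                           error_rate = 0.001, seed = 1L) {
  stopifnot(inherits(refs, "reference_pair"), inherits(profile, "cultivar_profile"),
            all(copy_numbers > 0), read_len < insert_mean,
            error_rate >= 0, error_rate < 1)
  set.seed(seed)
  q <- if (error_rate <= 0) 40L else min(40L, as.integer(round(-10 * log10(error_rate))))
  qual <- strrep(phred33(q), read_len)

  genomes <- list(mito = refs$mito_seq, plastid = refs$plastid_seq,
                  nuclear = refs$nuclear_seq)
  out1 <- list(); out2 <- list(); truth <- list()
  for (g in names(genomes)) {
    glen <- nchar(genomes[[g]])
    depth <- base_coverage * copy_numbers[[g]]
    n_pairs <- round(depth * glen / (2 * read_len))
    if (n_pairs < 1) next
    gint <- seq_to_int(genomes[[g]])
    insert <- pmin(glen, pmax(read_len, round(stats::rnorm(n_pairs, insert_mean, insert_sd))))
    start <- 1L + floor(stats::runif(n_pairs) * (glen - insert + 1))
    r2_start <- start + insert - read_len

    off <- 0:(read_len - 1L)
    w1 <- matrix(gint[outer(start, off, "+")], nrow = n_pairs)
    w2 <- matrix(gint[outer(r2_start, off, "+")], nrow = n_pairs)

    vars <- profile$variants[profile$variants$genome == g, , drop = FALSE]
    carried1 <- character(n_pairs); carried2 <- character(n_pairs)
    for (v in seq_len(nrow(vars))) {
      pos <- vars$position[v]
      alt <- base_to_int(vars$alt_base[v])
      covering <- start <= pos & pos <= start + insert - 1L
      carrier <- covering & stats::runif(n_pairs) < vars$allele_fraction[v]
      tag <- paste0(pos, ":", vars$alt_base[v])
      in1 <- carrier & pos <= start + read_len - 1L
      if (any(in1)) {
        w1[cbind(which(in1), pos - start[in1] + 1L)] <- alt
        carried1[in1] <- ifelse(carried1[in1] == "", tag, paste(carried1[in1], tag, sep = ","))
      }
      in2 <- carrier & pos >= r2_start
      if (any(in2)) {
        w2[cbind(which(in2), pos - r2_start[in2] + 1L)] <- alt
        carried2[in2] <- ifelse(carried2[in2] == "", tag, paste(carried2[in2], tag, sep = ","))
      }
    }
    w1 <- apply_errors(w1, error_rate)
    w2 <- apply_errors(w2, error_rate)

    ids <- sprintf("%s_%s_%06d", profile$name, g, seq_len(n_pairs))
    out1[[g]] <- data.frame(id = paste0(ids, "/1"), seq = rows_to_seq(w1),
                            qual = qual)
    out2[[g]] <- data.frame(id = paste0(ids, "/2"),
                            seq = revcomp(rows_to_seq(w2)), qual = qual)
    truth[[g]] <- data.frame(
      read_id = c(paste0(ids, "/1"), paste0(ids, "/2")),
      genome = g,
      start = c(start, r2_start),
      strand = rep(c("+", "-"), each = n_pairs),
      mate = rep(1:2, each = n_pairs),
      insert = c(insert, insert),
      variants = c(carried1, carried2))
  }
  reads1 <- do.call(rbind, out1); reads2 <- do.call(rbind, out2)
  if (is.null(reads1) || nrow(reads1) == 0) {
    warning("coverage too low: zero read pairs simulated")
    empty <- data.frame(id = character(0), seq = character(0), qual = character(0))
    return(list(reads1 = empty, reads2 = empty,
                truth = data.frame(read_id = character(0), genome = character(0),
                                   start = integer(0), strand = character(0),
                                   mate = integer(0), insert = integer(0),
                                   variants = character(0))))
  }
  rownames(reads1) <- rownames(reads2) <- NULL
  truth <- do.call(rbind, truth); rownames(truth) <- NULL
  list(reads1 = reads1, reads2 = reads2, truth = truth)
}

## i.i.d. substitution errors on an integer base matrix.
apply_errors <- function(w, error_rate) {
  if (error_rate <= 0) return(w)
  idx <- which(stats::runif(length(w)) < error_rate)
  if (length(idx)) {
    shift <- sample.int(3, length(idx), replace = TRUE)
    w[idx] <- ((w[idx] - 1L + shift) %% 4L) + 1L
  }
  w
}

## Integer base matrix (reads x positions) -> character vector of sequences.
rows_to_seq <- function(w) {
  cols <- lapply(seq_len(ncol(w)), function(j) DNA_BASES[w[, j]])
  do.call(paste0, cols)
}
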
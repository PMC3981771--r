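test_that("the seed index enumerates k-mer occurrences exactly", {
  idx <- build_index("ACGTACGT", k = 4)
  expect_equal(sort(orgsnp:::index_lookup(idx, "ACGT")), c(1L, 5L))
  expect_equal(orgsnp:::index_lookup(idx, "AAAA"), integer(0))
  set.seed(1)
  ref <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE), collapse = "")
  idx <- build_index(ref, k = 15)
  total <- sum(eapply(idx$env, length) |> unlist())
  expect_equal(total, 2000 - 15 + 1)
  expect_error(build_index("ACGT", k = 8), "exceeds")
})

test_that("exact reads map to their origin; duplicated loci give MAPQ 0", {
  set.seed(2)
  left <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  dup <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE), collapse = "")
  mid <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE), collapse = "")
  ref <- paste0(left, dup, mid, dup)
  idx <- build_index(ref)
  r <- map_read(substr(ref, 101, 200), idx)
  expect_true(r$mapped)
  expect_equal(r$pos, 101L)
  expect_equal(r$mismatches, 0L)
  expect_gte(r$mapq, 20L)
  # read wholly inside the duplicated segment: exact tie, MAPQ 0
  r2 <- map_read(substr(ref, 401, 500), idx)
  expect_true(r2$mapped)
  expect_equal(r2$mapq, 0L)
})

test_that("map_read agrees with the exhaustive Hamming-scan oracle", {
  set.seed(3)
  ref <- paste(sample(c("A", "C", "G", "T"), 1500, replace = TRUE), collapse = "")
  idx <- build_index(ref)
  reads <- character(0)
  starts <- sample(1400, 40)
  for (s in starts) {
    r <- substr(ref, s, s + 99)
    nmut <- sample(0:3, 1)
    if (nmut > 0) {
      v <- strsplit(r, "")[[1]]
      at <- sample(100, nmut)
      v[at] <- vapply(v[at], function(b) sample(setdiff(c("A","C","G","T"), b), 1), "")
      r <- paste(v, collapse = "")
    }
    if (sample(c(TRUE, FALSE), 1)) r <- revcomp(r)
    reads <- c(reads, r)
  }
  for (r in reads) {
    mine <- map_read(r, idx)
    oracle <- brute_force_map(r, ref)
    expect_equal(mine$mapped, oracle$mapped)
    if (mine$mapped) {
      expect_equal(mine$mismatches, oracle$mismatches)
      expect_equal(mine$pos, oracle$pos)
      expect_equal(mine$mapq, oracle$mapq)
    }
  }
})

test_that("reported placements have the reported Hamming distance", {
  refs <- simulate_references(plastid_len = 2000, mito_len = 3000,
                              nuclear_len = 1000, seed = 13)
  prof <- simulate_cultivar(refs, n_mito_snps = 3, n_plastid_snps = 2, seed = 13)
  sim <- simulate_reads(refs, prof, base_coverage = 5, error_rate = 0.01, seed = 14)
  aln <- map_library(sim$reads1, sim$reads2, refs$mito_seq, "mito")
  mapped <- aln[aln$mapped, ]
  for (i in sample(nrow(mapped), min(100, nrow(mapped)))) {
    seg <- substr(refs$mito_seq, mapped$pos[i], mapped$pos[i] + nchar(mapped$seq[i]) - 1)
    expect_equal(sum(strsplit(seg, "")[[1]] != strsplit(mapped$seq[i], "")[[1]]),
                 mapped$nm[i])
  }
})

test_that("error-free unique-region reads map at their truth position", {
  refs <- simulate_references(plastid_len = 2000, mito_len = 4000,
                              nuclear_len = 1000, transfer_fraction = 0, seed = 21)
  prof <- simulate_cultivar(refs, n_mito_snps = 0, n_plastid_snps = 0, seed = 21)
  sim <- simulate_reads(refs, prof,
                        copy_numbers = c(plastid = 0.01, mito = 1, nuclear = 0.01),
                        base_coverage = 30, error_rate = 0, seed = 22)
  aln <- map_library(sim$reads1, sim$reads2, refs$mito_seq, "mito")
  tru <- sim$truth
  m <- match(aln$qname, tru$read_id)
  mito_reads <- tru$genome[m] == "mito"
  at_truth <- aln$mapped & aln$pos == tru$start[m]
  expect_gte(mean(at_truth[mito_reads]), 0.99)
  # the same library mapped to the plastid reference: without transfers,
  # essentially nothing of mitochondrial origin maps
  aln_p <- map_library(sim$reads1, sim$reads2, refs$plastid_seq, "plastid")
  expect_equal(sum(aln_p$mapped & tru$genome[match(aln_p$qname, tru$read_id)] == "mito"), 0)
})

test_that("only reads from transfer segments cross-map to the plastid", {
  refs <- simulate_references(plastid_len = 4000, mito_len = 8000,
                              transfer_fraction = 0.2, n_segments = 2,
                              divergence = 0.02, nuclear_len = 1000, seed = 31)
  prof <- simulate_cultivar(refs, n_mito_snps = 0, n_plastid_snps = 0, seed = 31)
  sim <- simulate_reads(refs, prof,
                        copy_numbers = c(plastid = 0.01, mito = 1, nuclear = 0.01),
                        base_coverage = 20, error_rate = 0, seed = 32)
  aln_p <- map_library(sim$reads1, sim$reads2, refs$plastid_seq, "plastid")
  tru <- sim$truth
  m <- match(aln_p$qname, tru$read_id)
  hits <- which(aln_p$mapped & tru$genome[m] == "mito")
  tr <- refs$transfers
  overlap <- vapply(hits, function(i) {
    s <- tru$start[m[i]]; e <- s + 99
    max(0, max(pmin(e, tr$mito_end) - pmax(s, tr$mito_start) + 1))
  }, 1)
  # every cross-mapping mito read lies (almost) wholly inside a segment
  expect_true(all(overlap >= 80))
  # and reads wholly inside segments do cross-map in numbers
  expect_gt(length(hits), 10)
})

test_that("mate count mismatch is rejected", {
  r1 <- data.frame(id = "a/1", seq = "ACGTACGTACGTACGT", qual = "IIIIIIIIIIIIIIII")
  expect_error(map_library(r1, r1[0, ], "ACGTACGTACGTACGTACGT", "x"),
               "mate count")
})
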
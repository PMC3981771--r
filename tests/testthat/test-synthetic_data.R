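test_that("simulated references honour the transfer-fraction contract", {
  refs <- simulate_references(plastid_len = 20000, mito_len = 50000,
                              transfer_fraction = 0.103, n_segments = 5,
                              divergence = 0.02, seed = 11)
  tr <- refs$transfers
  expect_equal(nrow(tr), 5)
  # fraction recomputed from the emitted segments
  frac <- sum(tr$mito_end - tr$mito_start + 1) / 50000
  expect_gte(frac, 0.093); expect_lte(frac, 0.113)
  # equal lengths on both sides, non-overlapping on the mitochondrion
  expect_equal(tr$mito_end - tr$mito_start, tr$plastid_end - tr$plastid_start)
  o <- order(tr$mito_start)
  expect_true(all(tr$mito_start[o][-1] > tr$mito_end[o][-length(o)]))
  # mitochondrial copies diverge from their plastid source at ~2% per site
  mism <- mapply(function(ms, me, ps, pe) {
    sum(strsplit(substr(refs$mito_seq, ms, me), "")[[1]] !=
          strsplit(substr(refs$plastid_seq, ps, pe), "")[[1]])
  }, tr$mito_start, tr$mito_end, tr$plastid_start, tr$plastid_end)
  total_len <- sum(tr$mito_end - tr$mito_start + 1)
  expect_gt(sum(mism) / total_len, 0.005)
  expect_lt(sum(mism) / total_len, 0.04)
})

test_that("zero divergence and zero transfer fraction behave as identities", {
  refs0 <- simulate_references(plastid_len = 5000, mito_len = 8000,
                               nuclear_len = 1000, transfer_fraction = 0.1,
                               n_segments = 1, divergence = 0, seed = 3)
  tr <- refs0$transfers
  expect_equal(substr(refs0$mito_seq, tr$mito_start, tr$mito_end),
               substr(refs0$plastid_seq, tr$plastid_start, tr$plastid_end))
  none <- simulate_references(plastid_len = 5000, mito_len = 8000,
                              nuclear_len = 1000, transfer_fraction = 0,
                              n_segments = 3, seed = 3)
  expect_equal(nrow(none$transfers), 0)
  expect_error(simulate_references(plastid_len = 1000, mito_len = 50000,
                                   transfer_fraction = 0.5, seed = 1),
               "cannot source")
})

test_that("cultivar profiles have the requested composition", {
  refs <- simulate_references(plastid_len = 6000, mito_len = 9000,
                              nuclear_len = 1000, seed = 5)
  prof <- simulate_cultivar(refs, n_mito_snps = 0, n_plastid_snps = 8,
                            het_fraction = 1, af_range = c(0.4, 0.6), seed = 2)
  v <- prof$variants
  expect_equal(nrow(v), 8)
  expect_true(all(v$genome == "plastid"))
  expect_true(all(v$allele_fraction >= 0.4 & v$allele_fraction <= 0.6))
  expect_false(anyDuplicated(v$position) > 0)
  # ref_base actually matches the reference sequence
  expect_equal(substring(refs$plastid_seq, v$position, v$position), v$ref_base)
  expect_true(all(v$alt_base != v$ref_base))

  hom <- simulate_cultivar(refs, n_mito_snps = 6, n_plastid_snps = 3,
                           het_fraction = 0, seed = 7)
  expect_true(all(hom$variants$allele_fraction == 1))
  empty <- simulate_cultivar(refs, n_mito_snps = 0, n_plastid_snps = 0, seed = 1)
  expect_equal(nrow(empty$variants), 0)
  expect_error(simulate_cultivar(refs, af_range = c(0, 1.2), seed = 1), "af_range")
})

test_that("read simulation is deterministic and conserves truth records", {
  refs <- simulate_references(plastid_len = 3000, mito_len = 5000,
                              nuclear_len = 1000, seed = 8)
  prof <- simulate_cultivar(refs, n_mito_snps = 4, n_plastid_snps = 2, seed = 8)
  sim1 <- simulate_reads(refs, prof, base_coverage = 20, error_rate = 0.001, seed = 9)
  sim2 <- simulate_reads(refs, prof, base_coverage = 20, error_rate = 0.001, seed = 9)
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(sim1$reads1, f1); write_fastq(sim2$reads1, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(nrow(sim1$truth), nrow(sim1$reads1) + nrow(sim1$reads2))
  expect_false(anyDuplicated(sim1$truth$read_id) > 0)
})

test_that("error-free reads match their truth placement exactly", {
  refs <- simulate_references(plastid_len = 3000, mito_len = 5000,
                              nuclear_len = 1000, transfer_fraction = 0,
                              seed = 4)
  prof <- simulate_cultivar(refs, n_mito_snps = 0, n_plastid_snps = 0, seed = 4)
  sim <- simulate_reads(refs, prof, base_coverage = 10, error_rate = 0, seed = 5)
  genomes <- c(mito = refs$mito_seq, plastid = refs$plastid_seq,
               nuclear = refs$nuclear_seq)
  tru <- sim$truth
  reads <- rbind(sim$reads1, sim$reads2)
  m <- match(tru$read_id, reads$id)
  for (i in sample(nrow(tru), 200)) {
    g <- genomes[[tru$genome[i]]]
    expected <- substr(g, tru$start[i], tru$start[i] + 99)
    got <- reads$seq[m[i]]
    if (tru$mate[i] == 2) got <- revcomp(got)
    expect_identical(got, expected)
  }
})

test_that("per-genome depth scales with copy number", {
  refs <- simulate_references(plastid_len = 4000, mito_len = 4000,
                              nuclear_len = 1000, transfer_fraction = 0, seed = 6)
  prof <- simulate_cultivar(refs, n_mito_snps = 0, n_plastid_snps = 0, seed = 6)
  sim <- simulate_reads(refs, prof,
                        copy_numbers = c(plastid = 5, mito = 1, nuclear = 0.01),
                        base_coverage = 50, error_rate = 0, seed = 7)
  # depth from truth intervals at interior sites
  depth_at <- function(genome, pos) {
    tru <- sim$truth[sim$truth$genome == genome, ]
    sum(tru$start <= pos & pos <= tru$start + 99)
  }
  sites <- seq(500, 3500, by = 100)
  ratio <- mean(vapply(sites, depth_at, 1, genome = "plastid")) /
    mean(vapply(sites, depth_at, 1, genome = "mito"))
  expect_gte(ratio, 4); expect_lte(ratio, 6)
})

test_that("heteroplasmic variants appear on reads at their allele fraction", {
  refs <- simulate_references(plastid_len = 3000, mito_len = 3000,
                              nuclear_len = 1000, transfer_fraction = 0, seed = 2)
  prof <- simulate_cultivar(refs, n_mito_snps = 0, n_plastid_snps = 1,
                            het_fraction = 1, af_range = c(0.5, 0.5), seed = 3)
  pos <- prof$variants$position
  sim <- simulate_reads(refs, prof,
                        copy_numbers = c(plastid = 1, mito = 0.01, nuclear = 0.01),
                        base_coverage = 200, error_rate = 0, seed = 4)
  tru <- sim$truth[sim$truth$genome == "plastid", ]
  covering <- tru$start <= pos & pos <= tru$start + 99
  carrying <- grepl(paste0("^", pos, ":"), tru$variants) |
    grepl(paste0(",", pos, ":"), tru$variants)
  frac <- sum(carrying & covering) / sum(covering)
  expect_gte(frac, 0.4); expect_lte(frac, 0.6)
})
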
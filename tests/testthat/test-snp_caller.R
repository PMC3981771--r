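one_read_aln <- function(seq, pos = 1L, id = "r", mapq = 60L, qual = NULL) {
  data.frame(qname = id, flag = 0L, rname = "g", pos = pos, mapq = mapq,
             cigar = paste0(nchar(seq), "M"), seq = seq,
             qual = qual %||% strrep("I", nchar(seq)), nm = 0L,
             mapped = TRUE, strand = "+")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("pileup columns mirror the aligned bases", {
  ref <- "ACGTACGT"
  p1 <- pileup(one_read_aln("ACGT"), ref, min_mapq = 0)
  expect_equal(p1$depth[1:4], rep(1L, 4))
  expect_equal(p1$depth[5:8], rep(0L, 4))
  expect_equal(diag(as.matrix(p1[1:4, c("A", "C", "G", "T")])), rep(1L, 4))
  # overlapping disagreement produces two nonzero counts at one column
  a2 <- rbind(one_read_aln("ACGT"), one_read_aln("AGGT", id = "s"))
  p2 <- pileup(a2, ref, min_mapq = 0)
  expect_equal(p2$depth[2], 2L)
  expect_equal(sum(p2[2, c("A", "C", "G", "T")] > 0), 2)
  # MAPQ gate excludes reads at pileup time
  a3 <- rbind(one_read_aln("ACGT"), one_read_aln("ACGT", id = "t", mapq = 5L))
  expect_equal(pileup(a3, ref, min_mapq = 20)$depth[1], 1L)
  expect_error(pileup(one_read_aln("ACGT", pos = 7L), ref, min_mapq = 0),
               "past the reference end")
})

test_that("pileup depth matches the truth-interval expectation", {
  refs <- simulate_references(plastid_len = 2000, mito_len = 4000,
                              nuclear_len = 1000, transfer_fraction = 0, seed = 61)
  prof <- simulate_cultivar(refs, n_mito_snps = 0, n_plastid_snps = 0, seed = 61)
  sim <- simulate_reads(refs, prof,
                        copy_numbers = c(plastid = 0.01, mito = 1, nuclear = 0.01),
                        base_coverage = 100, error_rate = 0, seed = 62)
  aln <- map_library(sim$reads1, sim$reads2, refs$mito_seq, "mito")
  pile <- pileup(aln, refs$mito_seq)
  interior <- 300:3700
  tru <- sim$truth[sim$truth$genome == "mito", ]
  truth_depth <- vapply(seq(300, 3700, by = 50), function(pos) {
    sum(tru$start <= pos & pos <= tru$start + 99)
  }, 1)
  expect_lt(abs(mean(pile$depth[interior]) - mean(truth_depth)) / mean(truth_depth),
            0.1)
})

test_that("variant quality equals the direct binomial-tail summation", {
  direct <- function(depth, k, baseq) {
    e <- 10^(-baseq / 10)
    p <- sum(stats::dbinom(k:depth, depth, e))
    min(99, -10 * log10(p))
  }
  expect_equal(variant_quality(20, 0, 20), 0)
  expect_equal(variant_quality(20, 20, 20), 99)
  expect_equal(variant_quality(20, 1, 20), direct(20, 1, 20), tolerance = 1e-9)
  expect_equal(round(variant_quality(20, 1, 20), 1), 7.4)
  for (case in list(c(50, 3, 30), c(100, 10, 20), c(10, 2, 25), c(200, 2, 35))) {
    expect_equal(variant_quality(case[1], case[2], case[3]),
                 direct(case[1], case[2], case[3]), tolerance = 1e-8)
  }
})

test_that("call thresholds behave as stated and monotonically", {
  ref <- strrep("A", 30)
  # depth 9 with 9 alt reads: blocked by the depth gate
  reads <- do.call(rbind, lapply(1:9, function(i) {
    one_read_aln(paste0("C", strrep("A", 19)), id = paste0("r", i))
  }))
  pile <- pileup(reads, ref)
  expect_equal(nrow(call_snps(pile, call_thresholds())), 0)
  expect_equal(nrow(call_snps(pile, call_thresholds(min_depth = 9))), 1)
  # raising any threshold never adds a call
  refs <- simulate_references(plastid_len = 2000, mito_len = 3000,
                              nuclear_len = 1000, transfer_fraction = 0, seed = 71)
  prof <- simulate_cultivar(refs, n_mito_snps = 10, n_plastid_snps = 0,
                            het_fraction = 0.5, seed = 71)
  sim <- simulate_reads(refs, prof,
                        copy_numbers = c(plastid = 0.01, mito = 1, nuclear = 0.01),
                        base_coverage = 40, error_rate = 0.01, seed = 72)
  aln <- map_library(sim$reads1, sim$reads2, refs$mito_seq, "mito")
  base_pile <- pileup(aln, refs$mito_seq, min_mapq = 20)
  n_base <- nrow(call_snps(base_pile, call_thresholds()))
  expect_lte(nrow(call_snps(base_pile, call_thresholds(min_depth = 20))), n_base)
  expect_lte(nrow(call_snps(base_pile, call_thresholds(min_snp_quality = 30))), n_base)
  expect_lte(nrow(call_snps(pileup(aln, refs$mito_seq, min_mapq = 40),
                            call_thresholds(min_mapq = 40))), n_base)
})

test_that("planted homoplasmic SNPs are called exactly in a clean library", {
  refs <- simulate_references(plastid_len = 2000, mito_len = 4000,
                              nuclear_len = 1000, transfer_fraction = 0, seed = 81)
  prof <- simulate_cultivar(refs, n_mito_snps = 12, n_plastid_snps = 0,
                            het_fraction = 0, seed = 81)
  sim <- simulate_reads(refs, prof,
                        copy_numbers = c(plastid = 0.01, mito = 1, nuclear = 0.01),
                        base_coverage = 100, error_rate = 0, seed = 82)
  aln <- map_library(sim$reads1, sim$reads2, refs$mito_seq, "mito")
  pile <- pileup(aln, refs$mito_seq)
  calls <- call_snps(pile, call_thresholds(), cultivar = "CV1", genome = "mito")
  planted <- prof$variants$position
  # no calls at non-variant sites, and every adequately covered planted SNP
  # is recovered with the planted allele, homoplasmic
  expect_true(all(calls$position %in% planted))
  covered <- planted[pile$depth[planted] >= 10]
  expect_setequal(calls$position, covered)
  expect_true(all(calls$zygosity == "homoplasmic"))
  expect_equal(calls$alt, prof$variants$alt_base[match(calls$position, planted)])
})

test_that("zygosity classification reproduces the published depth patterns", {
  expect_equal(classify_zygosity(0, 20), "homoplasmic")
  expect_equal(classify_zygosity(9, 7), "heteroplasmic")
  expect_equal(classify_zygosity(1, 263), "heteroplasmic")
  expect_error(classify_zygosity(10, 0), "not a SNP")
  m <- mito_fixture()
  z <- classify_zygosity(m$depth_ref, m$depth_alt)
  expect_equal(sum(z == "heteroplasmic"), 15)
  expect_equal(z == "heteroplasmic", m$polymorphic_flag)
  p <- plastid_fixture()
  expect_true(all(classify_zygosity(p$depth_ref, p$depth_alt) == "heteroplasmic"))
})

test_that("heteroplasmic allele fractions are recovered from deep pileups", {
  refs <- simulate_references(plastid_len = 6000, mito_len = 1000,
                              nuclear_len = 1000, transfer_fraction = 0, seed = 91)
  prof <- simulate_cultivar(refs, n_mito_snps = 0, n_plastid_snps = 15,
                            het_fraction = 1, af_range = c(0.3, 0.7), seed = 91)
  sim <- simulate_reads(refs, prof,
                        copy_numbers = c(plastid = 1.2, mito = 0.02, nuclear = 0.02),
                        base_coverage = 100, error_rate = 0.001, seed = 92)
  aln <- map_library(sim$reads1, sim$reads2, refs$plastid_seq, "plastid")
  calls <- call_snps(pileup(aln, refs$plastid_seq), call_thresholds(),
                     genome = "plastid")
  v <- prof$variants
  m <- match(v$position, calls$position)
  called <- !is.na(m)
  obs <- calls$depth_alt[m[called]] /
    (calls$depth_ref[m[called]] + calls$depth_alt[m[called]])
  deep <- calls$read_depth[m[called]] >= 100
  expect_gte(sum(deep), 10)
  expect_gte(mean(abs(obs - v$allele_fraction[called])[deep] <= 0.15), 0.9)
})
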
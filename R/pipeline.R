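## End-to-end orchestration over synthetic data:
## simulate -> map -> cross-map filter -> call -> compare/summarise.
## The numbered scripts under analysis/ are thin drivers over these
## functions; every stage is also callable on its own.

#' Default pipeline configuration
#'
#' Stage parameters for a full synthetic run. Defaults reproduce the study
#' conditions the package emulates: ~10% of the mitochondrial genome
#' plastid-derived, plastid reads several-fold deeper than mitochondrial
#' ones, and the 10/20/15 SNP retention thresholds.
#'
#' @param seed master seed; per-stage seeds are derived from it.
#' @param plastid_len,mito_len,nuclear_len miniature genome sizes (bp).
#' @param transfer_fraction plastid-derived fraction of the mitochondrial
#'   genome.
#' @param divergence per-site divergence of transfer copies from their
#'   plastid source.
#' @param copy_numbers per-genome depth multipliers (plastid:mito defaults
#'   to 4:1, the coverage ratio total-DNA libraries show).
#' @param base_coverage depth of a copy-number-1 genome (the mitochondrion).
#' @param n_mito_snps,n_plastid_snps,het_fraction,af_range cultivar profile
#'   parameters (see [simulate_cultivar()]).
#' @param error_rate,read_len,insert_mean,insert_sd read simulation
#'   parameters.
#' @param n_segments number of transfer segments.
#' @param k,max_mismatch mapper parameters.
#' @param thresholds a [call_thresholds()] object.
#' @param bootstrap_replicates bootstrap replicate count for tree support.
#' @return named list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            plastid_len = 20000L, mito_len = 50000L,
                            nuclear_len = 100000L,
                            transfer_fraction = 0.103, divergence = 0.02,
                            copy_numbers = c(plastid = 4, mito = 1, nuclear = 0.02),
                            base_coverage = 100,
                            n_mito_snps = 10L, n_plastid_snps = 5L,
                            het_fraction = 0, af_range = c(0.2, 0.8),
                            error_rate = 0.001, read_len = 100L,
                            n_segments = 5L,
                            insert_mean = 300, insert_sd = 30,
                            k = 15L, max_mismatch = 5L,
                            thresholds = call_thresholds(),
                            bootstrap_replicates = 1000L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run the synthetic pipeline for one cultivar
#'
#' Simulates references and reads, maps the library to both organellar
#' references, derives the cross-mapped read set, and calls SNPs on each
#' genome before and after filtering.
#'
#' @param config a [pipeline_config()].
#' @param skip_filter if `TRUE`, the "after" call sets are computed without
#'   removing cross-mapped reads (for effect-of-filter comparisons).
#' @return list with `refs`, `profile`, `truth`, per-genome alignments
#'   (`aln`), filtered alignments (`aln_filtered`), SNP calls before/after
#'   filtering (`calls_unfiltered`, `calls_filtered`), filter `reports`, and
#'   the `crossmapped` identifier set.
#' @export
run_cultivar <- function(config = pipeline_config(), skip_filter = FALSE) {
  stopifnot(inherits(config, "run_config"))
  refs <- simulate_references(config$plastid_len, config$mito_len,
                              config$nuclear_len, config$transfer_fraction,
                              n_segments = config$n_segments,
                              divergence = config$divergence,
                              seed = config$seed)
  profile <- simulate_cultivar(refs, name = "CV1",
                               n_mito_snps = config$n_mito_snps,
                               n_plastid_snps = config$n_plastid_snps,
                               het_fraction = config$het_fraction,
                               af_range = config$af_range,
                               seed = config$seed + 1L)
  sim <- simulate_reads(refs, profile, copy_numbers = config$copy_numbers,
                        base_coverage = config$base_coverage,
                        read_len = config$read_len,
                        insert_mean = config$insert_mean,
                        insert_sd = config$insert_sd,
                        error_rate = config$error_rate,
                        seed = config$seed + 2L)
  aln <- list(
    mito = map_library(sim$reads1, sim$reads2, refs$mito_seq, "mito",
                       k = config$k, max_mismatch = config$max_mismatch),
    plastid = map_library(sim$reads1, sim$reads2, refs$plastid_seq, "plastid",
                          k = config$k, max_mismatch = config$max_mismatch))
  crossmapped <- crossmapped_ids(aln$mito, aln$plastid)
  aln_filtered <- if (skip_filter) aln else list(
    mito = apply_filter(aln$mito, crossmapped),
    plastid = apply_filter(aln$plastid, crossmapped))
  th <- config$thresholds
  call_on <- function(a, genome) {
    ref <- if (genome == "mito") refs$mito_seq else refs$plastid_seq
    call_snps(pileup(a, ref, min_mapq = th$min_mapq), th,
              cultivar = profile$name, genome = genome)
  }
  total <- nrow(sim$reads1) + nrow(sim$reads2)
  list(refs = refs, profile = profile, truth = sim$truth,
       aln = aln, aln_filtered = aln_filtered,
       calls_unfiltered = list(mito = call_on(aln$mito, "mito"),
                               plastid = call_on(aln$plastid, "plastid")),
       calls_filtered = list(mito = call_on(aln_filtered$mito, "mito"),
                             plastid = call_on(aln_filtered$plastid, "plastid")),
       reports = list(
         mito = filter_report(aln$mito, aln_filtered$mito,
                              nchar(refs$mito_seq), total, "mito"),
         plastid = filter_report(aln$plastid, aln_filtered$plastid,
                                 nchar(refs$plastid_seq), total, "plastid")),
       crossmapped = crossmapped)
}

#' The MTPT artifact experiment
#'
#' Quantifies the cross-mapping artifact and its elimination on one
#' synthetic cultivar: without filtering, plastid-origin reads co-assembling
#' onto the plastid-derived segments of the mitochondrial genome create
#' spurious heteroplasmic mitochondrial calls inside those segments; removing
#' every read that maps to both genomes eliminates them while genuine
#' homoplasmic mitochondrial SNPs outside the segments survive.
#'
#' This is a controlled experiment: sequencing error is switched off by
#' default so that every non-planted call is attributable to cross-mapping
#' rather than to error reads slipping past the binomial-tail quality score
#' in the low-depth ramps at segment edges. Retention counts a planted SNP
#' as recovered when its site is still called after filtering.
#'
#' @param config a [pipeline_config()]; the default turns sequencing error
#'   off and keeps every other study condition (transfer fraction 0.103,
#'   divergence 0.02, plastid:mito copies 4:1, 100x mitochondrial depth).
#' @return list: `n_spurious_unfiltered` / `n_spurious_filtered`
#'   (heteroplasmic mito calls inside transfer segments before/after
#'   filtering), `n_planted`, `n_recovered` and `recovery_rate` for the
#'   planted homoplasmic mitochondrial SNPs outside segments,
#'   `mito_read_retention` (fraction of mito-mapped reads surviving the
#'   filter), and the full `run`.
#' @export
artifact_experiment <- function(config = pipeline_config(error_rate = 0)) {
  run <- run_cultivar(config)
  tr <- run$refs$transfers
  in_transfer <- function(pos) {
    if (nrow(tr) == 0) return(rep(FALSE, length(pos)))
    vapply(pos, function(p) any(tr$mito_start <= p & p <= tr$mito_end), TRUE)
  }
  spurious <- function(calls) {
    sum(calls$zygosity == "heteroplasmic" & in_transfer(calls$position))
  }
  planted <- run$profile$variants
  planted <- planted[planted$genome == "mito" & planted$allele_fraction == 1, ]
  planted <- planted[!in_transfer(planted$position), ]
  recovered <- sum(planted$position %in% run$calls_filtered$mito$position)
  rep_m <- run$reports$mito
  list(n_spurious_unfiltered = spurious(run$calls_unfiltered$mito),
       n_spurious_filtered = spurious(run$calls_filtered$mito),
       n_planted = nrow(planted),
       n_recovered = recovered,
       recovery_rate = if (nrow(planted)) recovered / nrow(planted) else NA_real_,
       mito_read_retention = rep_m$reads_mapped_after_filtering / rep_m$reads_mapped,
       run = run)
}

#' Write a pipeline run to disk
#'
#' Serialises the outputs of [run_cultivar()] into a run directory: FASTA
#' references, SAM alignments (before/after filtering), VCF and TSV call
#' sets, the filter report, and a JSON summary recording the full resolved
#' configuration and seed.
#'
#' @param run result of [run_cultivar()].
#' @param config the [pipeline_config()] used.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  write_fasta(c(plastid = run$refs$plastid_seq, mito = run$refs$mito_seq,
                nuclear = run$refs$nuclear_seq), p("references.fa"))
  ref_lens <- c(mito = nchar(run$refs$mito_seq),
                plastid = nchar(run$refs$plastid_seq))
  for (g in c("mito", "plastid")) {
    write_sam(run$aln[[g]], ref_lens[g], p(paste0(g, ".sam")))
    write_sam(run$aln_filtered[[g]], ref_lens[g], p(paste0(g, ".filtered.sam")))
    write_vcf(run$calls_filtered[[g]], g, p(paste0(g, ".filtered.vcf")))
    utils::write.table(run$calls_filtered[[g]], p(paste0(g, ".calls.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  report <- rbind(run$reports$mito, run$reports$plastid)
  utils::write.table(report, p("filter_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- config
  cfg$thresholds <- unclass(cfg$thresholds)
  summary <- list(config = unclass(cfg),
                  seed = config$seed,
                  n_crossmapped = length(run$crossmapped),
                  calls = list(
                    mito = nrow(run$calls_filtered$mito),
                    plastid = nrow(run$calls_filtered$plastid)))
  jsonlite::write_json(summary, p("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(out_dir)
}
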
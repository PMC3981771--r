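#!/usr/bin/env Rscript

# Cohort analysis of the two published SNP tables bundled with the package:
# per-cultivar totals, unique SNPs, sharing spectra, zygosity and genomic
# context. Everything here is deterministic; outputs go to results/.

suppressMessages(library(orgsnp))
dir.create("results", showWarnings = FALSE)

summarise_genome <- function(which) {
  tab <- load_paper_table(which)
  ct <- cohort_table(tab)
  counts <- per_cultivar_counts(ct)
  uniq <- unique_snps(ct)
  spectrum <- sharing_spectrum(ct)
  zyg <- classify_zygosity(tab$depth_ref, tab$depth_alt)
  ctx <- summarize_contexts(tab)

  cat(sprintf("\n== %s genome ==\n", which))
  cat(sprintf("%d SNP records at %d distinct positions\n",
              nrow(tab), length(unique(tab$position))))
  cat(sprintf("per-cultivar SNPs: %d-%d\n", min(counts), max(counts)))
  cat(sprintf("heteroplasmic (both depths > 0): %d of %d\n",
              sum(zyg == "heteroplasmic"), nrow(tab)))
  cat(sprintf("unique to one cultivar: %d records; cultivars without any: %s\n",
              sum(lengths(uniq)),
              paste(names(uniq)[lengths(uniq) == 0], collapse = ", ")))
  cat("sharing spectrum (k cultivars -> positions):\n")
  print(spectrum)
  cat("context partition over distinct positions:\n")
  print(ctx)

  utils::write.table(data.frame(cultivar = names(counts), n_snps = counts,
                                n_unique = lengths(uniq)[names(counts)]),
                     file.path("results", paste0(which, "_per_cultivar.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  list(records = nrow(tab), positions = length(unique(tab$position)),
       per_cultivar = as.list(counts),
       heteroplasmic = sum(zyg == "heteroplasmic"),
       unique_records = sum(lengths(uniq)),
       cultivars_without_unique = names(uniq)[lengths(uniq) == 0],
       sharing_spectrum = as.list(spectrum),
       contexts = as.list(ctx))
}

summary <- list(mito = summarise_genome("mito"),
                plastid = summarise_genome("plastid"))
jsonlite::write_json(summary, "results/fixture_summary.json",
                     auto_unbox = TRUE, pretty = TRUE)
cat("\nwrote results/fixture_summary.json\n")
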
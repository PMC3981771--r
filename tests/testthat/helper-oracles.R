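# Independent oracles and shared fixtures. Each oracle re-derives the
# quantity it checks by the most direct method available (exhaustive
# enumeration, closed form, full retranslation), independently of the code
# path under test.

BASES <- c("A", "C", "G", "T")

# Exhaustive all-position Hamming scan over both strands; reproduces the
# mapper's placement contract (best = fewest mismatches, MAPQ from the gap
# to the second-best candidate among seedable placements is NOT modelled --
# the oracle considers every placement, which is strictly stronger).
brute_force_map <- function(read, reference, max_mismatch = 5L) {
  L <- nchar(read)
  ref <- strsplit(reference, "")[[1]]
  cand <- list()
  for (strand in c("+", "-")) {
    r <- if (strand == "+") read else revcomp(read)
    rv <- strsplit(r, "")[[1]]
    for (s in seq_len(length(ref) - L + 1)) {
      cand[[length(cand) + 1]] <- list(pos = s, strand = strand,
                                       mm = sum(ref[s:(s + L - 1)] != rv))
    }
  }
  mm <- vapply(cand, `[[`, 1, "mm")
  o <- order(mm)
  best <- mm[o[1]]
  if (best > max_mismatch) return(list(mapped = FALSE))
  tie <- sum(mm == best) >= 2
  second <- if (length(mm) >= 2) mm[o[2]] else max_mismatch + 1L
  list(mapped = TRUE, pos = cand[[o[1]]]$pos, strand = cand[[o[1]]]$strand,
       mismatches = best,
       mapq = if (tie) 0L else min(60L, 20L * (min(second, max_mismatch + 1L) - best)))
}

# Simulate a nucleotide matrix along a tree under Jukes-Cantor.
simulate_jc_matrix <- function(tree, n_sites) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  root <- tree$edge[nrow(tree$edge), 1]
  states <- vector("list", n_tip + tree$Nnode)
  states[[root]] <- sample.int(4, n_sites, replace = TRUE)
  for (i in rev(seq_len(nrow(tree$edge)))) {
    par <- tree$edge[i, 1]; chd <- tree$edge[i, 2]
    p_change <- 0.75 - 0.75 * exp(-4 * tree$edge.length[i] / 3)
    x <- states[[par]]
    mut <- stats::runif(n_sites) < p_change
    x[mut] <- ((x[mut] - 1L + sample.int(3, sum(mut), replace = TRUE)) %% 4L) + 1L
    states[[chd]] <- x
  }
  out <- matrix(BASES[unlist(states[seq_len(n_tip)])], nrow = n_tip,
                byrow = TRUE, dimnames = list(tree$tip.label, NULL))
  out
}

# Full-protein translation (table 11) for the retranslation oracle.
translate_protein <- function(cds) {
  gc <- Biostrings::getGeneticCode("11")
  paste(vapply(seq(1, nchar(cds) - 2, by = 3),
               function(i) gc[[substr(cds, i, i + 2)]], ""), collapse = "")
}

# Deterministic toy annotation: a plus-strand two-exon gene, its intron, and
# a minus-strand single-exon gene, on a 400 bp genome.
toy_annotation <- function(seed = 42) {
  set.seed(seed)
  genome <- paste(sample(BASES, 400, replace = TRUE), collapse = "")
  # make both CDSs length-divisible by 3: exons 21..50 + 61..90 (60 bp),
  # minus-strand exon 201..290 (90 bp)
  track <- feature_track(data.frame(
    feature_id = c("psaX", "psaX.e1", "psaX.i1", "psaX.e2", "matY", "matY.e1"),
    type = c("gene", "exon", "intron", "exon", "gene", "exon"),
    start = c(21, 21, 51, 61, 201, 201),
    end = c(90, 50, 60, 90, 290, 290),
    strand = c("+", "+", "+", "+", "-", "-"),
    gene = c("psaX", "psaX", "psaX", "psaX", "matY", "matY")))
  list(genome = genome, track = track)
}

# Cache for expensive shared computations within one test run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# The artifact experiment at study conditions (error-free controlled run);
# shared between the filter property tests and the acceptance suite.
artifact_fixture <- function() {
  cached("artifact", artifact_experiment(pipeline_config(seed = 101, error_rate = 0)))
}

mito_fixture <- function() cached("mito_table", load_paper_table("mito"))
plastid_fixture <- function() cached("plastid_table", load_paper_table("plastid"))
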
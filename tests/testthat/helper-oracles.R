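# Independent oracles used to validate the package's implementations.

# Hypergeometric upper tail by literal enumeration of all C(N, n) draws:
# successes are items 1..K; returns the fraction of draws with >= k
# successes. Only feasible for small N.
hyper_tail_enum <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= k)
}

# Brute-force greedy peak extraction with an explicit mask array: rescan
# the full vector for the unmasked argmax every round.
brute_extract_peaks <- function(values, start = 0, mask_window = 600,
                                floor = -Inf) {
  n <- length(values)
  masked <- rep(FALSE, n)
  half <- mask_window %/% 2
  pos <- integer(0); height <- numeric(0)
  repeat {
    best <- -Inf; best_i <- NA
    for (i in seq_len(n)) {
      if (!masked[i] && values[i] > best) {
        best <- values[i]; best_i <- i
      }
    }
    if (is.na(best_i) || !is.finite(best) || best < floor) break
    pos <- c(pos, start + best_i - 1L)
    height <- c(height, best)
    masked[max(1, best_i - half):min(n, best_i + half)] <- TRUE
  }
  data.frame(pos = pos, height = height)
}

# Positional brute-force mini-motif containment: check every anchor for
# triplet1 + gap + triplet2, on both strands, by substring comparison.
seq_contains_oracle <- function(seq, motif) {
  rc1 <- function(s) chartr("ACGTN", "TGCAN",
                            paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  check_one <- function(seq, t1, g, t2) {
    L <- nchar(seq)
    span <- 6 + g
    if (L < span) return(FALSE)
    for (i in 1:(L - span + 1)) {
      if (substr(seq, i, i + 2) == t1 &&
          substr(seq, i + 3 + g, i + 5 + g) == t2 &&
          !grepl("N", substr(seq, i + 3, i + 2 + g))) {
        return(TRUE)
      }
    }
    FALSE
  }
  check_one(seq, motif$triplet1, motif$gap, motif$triplet2) ||
    check_one(seq, rc1(motif$triplet2), motif$gap, rc1(motif$triplet1))
}

# Random uniform DNA sequence.
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Wrap a per-bp vector as a signal_track (tests construct these directly).
as_signal_track <- function(values, chrom = "chr1", start = 0) {
  structure(list(chrom = chrom, start = start, values = values,
                 experiment_id = "test"), class = "signal_track")
}

# A small two-species simulation with one conserved planted TF, shared by
# several tests. Sizes kept modest for runtime.
small_planted_sim <- function(seed = 1, n_targets = 30, amplitude = 2,
                              conservation = 0.5,
                              genes_per_chromosome = 120) {
  sim <- simulate_species_pair(
    spec_a = species_spec("SpA", n_chromosomes = 1,
                          genes_per_chromosome = genes_per_chromosome,
                          probe_density = 20),
    spec_b = species_spec("SpB", n_chromosomes = 1,
                          genes_per_chromosome = genes_per_chromosome,
                          probe_density = 17),
    ortholog_fraction = 0.8, seed = seed)
  regs <- sample_target_regions(sim, "SpA", n_targets,
                                ortholog_only = TRUE, seed = seed)
  plant_binding_sites(sim, "SpA", "TF1", regs, minimotif("CAC", 0, "GTG"),
                      amplitude = amplitude, conservation = conservation,
                      seed = seed)
}
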
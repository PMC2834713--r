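# Spaced-triplet ("mini-motif") enrichment: every motif of two nucleotide
# triplets separated by a fixed gap of 0-15 arbitrary bases
# (XXX n(0-15) XXX) is counted, on either strand, in 300 bp peak-window
# sequences and ranked by hypergeometric enrichment against
# composition-preserving shuffled sequences.

MM_GAP_MAX <- 15L

#' Construct a mini-motif
#'
#' A spaced dyad: two fixed 3-mers over ACGT separated by a fixed gap of
#' 0-15 arbitrary bases. A motif and its reverse complement (which swaps
#' and complements the triplets, keeping the gap) describe the same
#' double-stranded element; [mm_canonical()] picks the lexicographically
#' smaller of the two as the canonical form.
#'
#' @param triplet1,triplet2 3-letter strings over ACGT.
#' @param gap integer gap length, 0-15.
#' @return an object of class `minimotif`.
#' @examples
#' minimotif("CAC", 0, "GTG")  # the E-box CACGTG
#' @export
minimotif <- function(triplet1, gap, triplet2) {
  triplet1 <- toupper(triplet1); triplet2 <- toupper(triplet2)
  if (!grepl("^[ACGT]{3}$", triplet1) || !grepl("^[ACGT]{3}$", triplet2)) {
    stop("triplets must be 3 letters over ACGT")
  }
  gap <- as.integer(gap)
  if (gap < 0 || gap > MM_GAP_MAX) stop("gap must be in 0..15")
  structure(list(triplet1 = triplet1, gap = gap, triplet2 = triplet2),
            class = "minimotif")
}

#' @export
format.minimotif <- function(x, ...) {
  sprintf("%s(n%d)%s", x$triplet1, x$gap, x$triplet2)
}

#' @export
print.minimotif <- function(x, ...) {
  cat("minimotif", format(x), "\n")
  invisible(x)
}

#' Reverse complement of a mini-motif
#' @param motif a [minimotif()].
#' @return the reverse-complement `minimotif` (triplets swapped and
#'   complemented, gap unchanged).
#' @export
mm_revcomp <- function(motif) {
  minimotif(revcomp_chr(motif$triplet2), motif$gap,
            revcomp_chr(motif$triplet1))
}

#' Canonical form of a mini-motif
#'
#' The lexicographic minimum of the motif and its reverse complement;
#' palindromic motifs are their own canonical form. Canonicalization
#' partitions the 65,536 raw motifs into 33,280 double-stranded classes.
#'
#' @param motif a [minimotif()].
#' @return a `minimotif`.
#' @export
mm_canonical <- function(motif) {
  rc <- mm_revcomp(motif)
  if (mm_encode(motif) <= mm_encode(rc)) motif else rc
}

# Integer codes: triplet index in 0..63 (base-4 over A<C<G<T), motif id
# = t1 * 1024 + gap * 64 + t2, in 0..65535. Id order equals lexicographic
# order of (triplet1, triplet2) at fixed gap.
mm_encode <- function(motif) {
  tr <- function(t) {
    d <- match(strsplit(t, "")[[1]], DNA_BASES) - 1L
    16L * d[1] + 4L * d[2] + d[3]
  }
  tr(motif$triplet1) * 1024L + motif$gap * 64L + tr(motif$triplet2)
}

mm_decode <- function(id) {
  t1 <- id %/% 1024L
  g <- (id %% 1024L) %/% 64L
  t2 <- id %% 64L
  tri <- function(x) {
    paste0(DNA_BASES[x %/% 16L + 1L], DNA_BASES[(x %% 16L) %/% 4L + 1L],
           DNA_BASES[x %% 4L + 1L])
  }
  minimotif(tri(t1), g, tri(t2))
}

# Vectorized reverse-complement id table over all 65,536 ids.
mm_rc_table <- function() {
  id <- 0:65535
  t1 <- id %/% 1024L
  g <- (id %% 1024L) %/% 64L
  t2 <- id %% 64L
  rc3 <- function(t) {
    16L * (3L - t %% 4L) + 4L * (3L - (t %% 16L) %/% 4L) + (3L - t %/% 16L)
  }
  rc3(t2) * 1024L + g * 64L + rc3(t1)
}

#' Does a sequence contain a mini-motif?
#'
#' TRUE when `triplet1`, exactly `gap` ACGT bases, then `triplet2` occurs
#' in the sequence, or the reverse-complement motif does (double-stranded
#' matching). `N` never matches, neither in the triplets nor in the gap.
#'
#' @param seq character string over ACGTN.
#' @param motif a [minimotif()].
#' @return logical.
#' @export
sequence_contains <- function(seq, motif) {
  seq <- toupper(seq)
  pat <- function(m) {
    sprintf("%s[ACGT]{%d}%s", m$triplet1, m$gap, m$triplet2)
  }
  grepl(pat(motif), seq) || grepl(pat(mm_revcomp(motif)), seq)
}

#' Composition-preserving sequence randomization
#'
#' Per-sequence mononucleotide shuffle: each output sequence is a seeded
#' random permutation of the bases of the corresponding input sequence, so
#' length and base composition are preserved exactly.
#'
#' @param seqs character vector of sequences.
#' @param seed RNG seed.
#' @return character vector of shuffled sequences, same length.
#' @export
shuffle_sequences <- function(seqs, seed) {
  withr::with_seed(seed, {
    vapply(seqs, function(s) {
      paste(sample(strsplit(s, "")[[1]]), collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
}

# For one sequence, the set of raw motif ids present on the forward strand
# (double-stranded containment is resolved later via the rc table).
mm_present_ids <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  code <- match(chars, DNA_BASES) - 1L  # N -> NA
  L <- length(code)
  if (L < 6) return(integer(0))
  trip <- 16L * code[1:(L - 2)] + 4L * code[2:(L - 1)] + code[3:L]
  ids <- integer(0)
  for (g in 0:MM_GAP_MAX) {
    last <- L - 5L - g
    if (last < 1) break
    i <- seq_len(last)
    v <- trip[i] * 1024L + g * 64L + trip[i + 3L + g]
    ids <- c(ids, v[!is.na(v)])
  }
  unique(ids)
}

#' Extract fixed-width sequence windows around peaks
#'
#' A window of `window_bp` (default 300) centered on each 1 bp peak,
#' clipped at chromosome ends (and then flagged truncated). `top_quarter`
#' keeps the top 25\% of peaks by height before extraction, mirroring the
#' use of the strongest peaks for motif discovery. Windows with more than
#' 10\% `N` are flagged.
#'
#' @param peaks peaks data.frame (columns `chrom`, `pos`, `height`).
#' @param genome named character vector of chromosome sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param window_bp window width.
#' @param subset `"all"` or `"top_quarter"`.
#' @return data.frame `(peak_id, chrom, start, end, seq, truncated,
#'   high_n)`; the `start`/`end` are the 0-based half-open window bounds.
#' @export
extract_peak_windows <- function(peaks, genome, window_bp = 300,
                                 subset = c("all", "top_quarter")) {
  subset <- match.arg(subset)
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (subset == "top_quarter" && nrow(peaks) > 0) {
    keep <- ceiling(nrow(peaks) * 0.25)
    peaks <- peaks[order(-peaks$height), , drop = FALSE][seq_len(keep), ,
                                                         drop = FALSE]
  }
  half <- window_bp %/% 2
  rows <- lapply(seq_len(nrow(peaks)), function(i) {
    chr <- peaks$chrom[i]
    if (!chr %in% names(genome)) {
      stop("chromosome ", chr, " missing from genome")
    }
    len <- nchar(genome[[chr]])
    s <- max(0, peaks$pos[i] - half)
    e <- min(len, peaks$pos[i] + half)
    sq <- substr(genome[[chr]], s + 1, e)
    data.frame(peak_id = sprintf("%s_%d", chr, peaks$pos[i]), chrom = chr,
               start = s, end = e, seq = sq,
               truncated = (e - s) < window_bp,
               high_n = mean(strsplit(sq, "")[[1]] == "N") > 0.1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(peak_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      seq = character(0), truncated = logical(0),
                      high_n = logical(0))
  }
  out
}

#' Exhaustive mini-motif enrichment scan
#'
#' Enumerates all 64 x 16 x 64 = 65,536 (triplet1, gap, triplet2) motifs.
#' For each, `k_real` is the number of real sequences containing the motif
#' or its reverse complement and `k_rand` the same count in a
#' composition-preserving shuffled set of equal size; the enrichment is the
#' hypergeometric tail of drawing the real set from the pooled real+random
#' urn: `p = P(X >= k_real)` with `K = k_real + k_rand`, `n = n_real`,
#' `N = n_real + n_rand`. Reverse-complement motif pairs are merged to
#' their canonical form before ranking (33,280 classes).
#'
#' @param windows a window table from [extract_peak_windows()], or a
#'   character vector of sequences.
#' @param seed seed for the shuffle.
#' @param top_k return only the best `top_k` motifs (default all).
#' @param shuffled optional pre-shuffled comparison sequences (otherwise
#'   generated from `windows` with `seed`).
#' @return data.frame `(triplet1, gap, triplet2, motif, k_real, n_real,
#'   k_rand, n_rand, p, p_bonferroni, rank)`, ascending in `p`.
#' @export
minimotif_scan <- function(windows, seed = 1, top_k = NULL,
                           shuffled = NULL) {
  seqs <- if (is.data.frame(windows)) windows$seq else windows
  if (length(seqs) < 10) warning("fewer than 10 sequences: scan will be noisy")
  if (is.null(shuffled)) shuffled <- shuffle_sequences(seqs, seed)
  rc <- mm_rc_table()
  count_canonical <- function(ss) {
    counts <- integer(65536)
    for (s in ss) {
      ids <- mm_present_ids(s)
      if (length(ids) == 0) next
      can <- unique(pmin(ids, rc[ids + 1L]))
      counts[can + 1L] <- counts[can + 1L] + 1L
    }
    counts
  }
  k_real <- count_canonical(seqs)
  k_rand <- count_canonical(shuffled)
  canon_ids <- which(0:65535 <= rc) - 1L  # ids that are their own minimum
  k_real <- k_real[canon_ids + 1L]
  k_rand <- k_rand[canon_ids + 1L]
  n_real <- length(seqs); n_rand <- length(shuffled)
  p <- stats::phyper(k_real - 1, m = k_real + k_rand,
                     n = (n_real - k_real) + (n_rand - k_rand),
                     k = n_real, lower.tail = FALSE)
  t1 <- canon_ids %/% 1024L
  g <- (canon_ids %% 1024L) %/% 64L
  t2 <- canon_ids %% 64L
  tri <- function(x) {
    paste0(DNA_BASES[x %/% 16L + 1L], DNA_BASES[(x %% 16L) %/% 4L + 1L],
           DNA_BASES[x %% 4L + 1L])
  }
  res <- data.frame(triplet1 = tri(t1), gap = g, triplet2 = tri(t2),
                    motif = sprintf("%s(n%d)%s", tri(t1), g, tri(t2)),
                    k_real = k_real, n_real = n_real, k_rand = k_rand,
                    n_rand = n_rand, p = p,
                    p_bonferroni = pmin(1, p * length(canon_ids)),
                    stringsAsFactors = FALSE)
  res <- res[order(res$p, -res$k_real, res$motif), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  if (!is.null(top_k)) res <- head(res, top_k)
  res
}

#' Match a degenerate (IUPAC) consensus against a sequence
#'
#' Aligns the consensus to the sequence at a fixed offset and counts, over
#' the non-N consensus positions, how many sequence bases fall in the IUPAC
#' class of the consensus.
#'
#' @param consensus IUPAC string (N positions are skipped).
#' @param seq sequence to compare (length must cover the consensus at the
#'   given offset).
#' @param offset 0-based offset of the consensus start within `seq`.
#' @return list with `n_defined`, `n_matched` and `positions` (1-based
#'   consensus positions that matched).
#' @export
match_degenerate_consensus <- function(consensus, seq, offset = 0) {
  consensus <- toupper(consensus); seq <- toupper(seq)
  L <- nchar(consensus)
  if (offset < 0 || offset + L > nchar(seq)) {
    stop("consensus does not fit in sequence at offset ", offset,
         " (supply an offset for unequal lengths)")
  }
  frag <- substr(seq, offset + 1, offset + L)
  cc <- strsplit(consensus, "")[[1]]
  sc <- strsplit(frag, "")[[1]]
  iupac <- Biostrings::IUPAC_CODE_MAP
  defined <- which(cc != "N")
  matched <- defined[vapply(defined, function(i) {
    cls <- iupac[[cc[i]]]
    !is.na(cls) && grepl(sc[i], cls, fixed = TRUE)
  }, logical(1))]
  list(n_defined = length(defined), n_matched = length(matched),
       positions = matched)
}

# IUPAC consensus -> regex character classes.
iupac_to_regex <- function(consensus) {
  map <- Biostrings::IUPAC_CODE_MAP
  paste(vapply(strsplit(toupper(consensus), "")[[1]], function(ch) {
    cls <- if (ch == "N") "ACGT" else map[[ch]]
    if (is.null(cls) || is.na(cls)) stop("bad IUPAC letter: ", ch)
    if (nchar(cls) == 1) cls else sprintf("[%s]", cls)
  }, character(1)), collapse = "")
}

#' Map motif hits across a regulon's promoter regions
#'
#' Scans the sequence of each promoter region carrying a peak of the
#' regulon for a mini-motif or IUPAC consensus, on both strands, and
#' reports each hit's offset relative to the 5' end (start codon side) of
#' every gene the region is promoter to: negative offsets are upstream of
#' the gene. Palindromic hits found at the same position on both strands
#' are reported once with strand `"both"`.
#'
#' @param regulon a `regulon` whose peaks carry `region_id`s.
#' @param motif a [minimotif()] or an IUPAC consensus string.
#' @param regions intergenic region table.
#' @param genome named character vector or `DNAStringSet`.
#' @param genes gene annotation table.
#' @return data.frame `(region_id, gene_id, position, offset, strand)`.
#' @export
motif_position_map <- function(regulon, motif, regions, genome, genes) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  pat_fwd <- if (inherits(motif, "minimotif")) {
    sprintf("%s[ACGT]{%d}%s", motif$triplet1, motif$gap, motif$triplet2)
  } else iupac_to_regex(motif)
  pat_rev <- if (inherits(motif, "minimotif")) {
    rc <- mm_revcomp(motif)
    sprintf("%s[ACGT]{%d}%s", rc$triplet1, rc$gap, rc$triplet2)
  } else iupac_to_regex(revcomp_chr(motif))
  region_ids <- unique(stats::na.omit(regulon$peaks$region_id))
  rows <- list()
  for (rid in region_ids) {
    r <- regions[regions$region_id == rid, , drop = FALSE]
    if (nrow(r) == 0) next
    sq <- substr(genome[[r$chrom]], r$start + 1, r$end)
    hits <- data.frame(at = integer(0), strand = character(0))
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") pat_fwd else pat_rev
      m <- gregexpr(pat, sq)[[1]]
      if (m[1] != -1) {
        hits <- rbind(hits, data.frame(at = as.integer(m), strand = strand,
                                       stringsAsFactors = FALSE))
      }
    }
    if (nrow(hits) == 0) next
    # collapse palindromic double hits at the same offset
    both <- intersect(hits$at[hits$strand == "+"],
                      hits$at[hits$strand == "-"])
    hits <- hits[!(hits$at %in% both & hits$strand == "-"), , drop = FALSE]
    hits$strand[hits$at %in% both] <- "both"
    for (j in seq_len(nrow(hits))) {
      pos <- r$start + hits$at[j] - 1L  # 0-based genomic hit start
      for (gid in r$promoter_of[[1]]) {
        gn <- genes[genes$gene_id == gid, , drop = FALSE]
        offset <- if (gn$strand == "+") pos - gn$start else
          -(pos - gn$end)
        rows[[length(rows) + 1]] <- data.frame(
          region_id = rid, gene_id = gid, position = pos,
          offset = as.integer(offset), strand = hits$strand[j],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(region_id = character(0), gene_id = character(0),
                      position = integer(0), offset = integer(0),
                      strand = character(0))
  }
  out
}
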
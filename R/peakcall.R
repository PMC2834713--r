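# Peak detection on tiling-array probe tracks: Gaussian blur of probe
# values, natural cubic spline interpolation to every base pair, greedy
# extraction of 1 bp peaks under a 600 bp masking window, Z-score
# significance calling, promoter-based target assignment, and ORF-level
# differential signal between two conditions.

#' Gaussian blur of probe-level log2 enrichment values
#'
#' Replaces each probe value by a Gaussian-kernel weighted average of the
#' probe values on the same chromosome, with weights
#' `exp(-d^2 / (2 sigma^2))` over the base-pair distance `d`, normalized to
#' sum to one per probe. `sigma_bp = 0` is the identity. Contributions
#' beyond 4 sigma (weight < 3.4e-4) are dropped for linear-time evaluation.
#'
#' @param track a [probe_track()].
#' @param sigma_bp kernel standard deviation in base pairs (default 50,
#'   about one probe spacing at 17-20 probes/kb).
#' @return a new `probe_track` with smoothed values; `mean_raw`/`sd_raw`
#'   are carried over from the input (Z statistics stay on raw values).
#' @export
gaussian_blur <- function(track, sigma_bp = 50) {
  stopifnot(inherits(track, "probe_track"), sigma_bp >= 0)
  if (nrow(track$probes) == 0) stop("empty probe track")
  if (sigma_bp == 0) return(track)
  cutoff <- 4 * sigma_bp
  probes <- track$probes
  smoothed <- unlist(lapply(split(seq_len(nrow(probes)), probes$chrom),
                            function(idx) {
    pos <- probes$pos[idx]
    val <- probes$value[idx]
    n <- length(pos)
    num <- val
    den <- rep(1, n)
    j <- 1L
    while (j < n) {
      d <- pos[(1 + j):n] - pos[1:(n - j)]
      if (all(d > cutoff)) break
      w <- exp(-d^2 / (2 * sigma_bp^2))
      w[d > cutoff] <- 0
      num[(1 + j):n] <- num[(1 + j):n] + w * val[1:(n - j)]
      num[1:(n - j)] <- num[1:(n - j)] + w * val[(1 + j):n]
      den[(1 + j):n] <- den[(1 + j):n] + w
      den[1:(n - j)] <- den[1:(n - j)] + w
      j <- j + 1L
    }
    num / den
  }), use.names = FALSE)
  ord <- order(probes$chrom, probes$pos)  # split() used chrom order
  probes2 <- probes[ord, , drop = FALSE]
  probes2$value <- smoothed
  out <- track
  out$probes <- probes2
  rownames(out$probes) <- NULL
  out
}

#' Interpolate a probe track to every base pair
#'
#' Fits a natural cubic spline through the (position, value) probe points of
#' one chromosome and evaluates it at every integer base pair between the
#' outermost probes (no extrapolation). Values at probe positions equal the
#' probe values exactly.
#'
#' @param track a [probe_track()].
#' @param chrom chromosome to interpolate (defaults to the only one).
#' @param from,to optional 0-based span to clip the evaluated range to.
#' @return an object of class `signal_track`: list with `chrom`, `start`
#'   (first evaluated bp), `values` (one per bp), `experiment_id`.
#' @export
interpolate_to_bp <- function(track, chrom = NULL, from = NULL, to = NULL) {
  stopifnot(inherits(track, "probe_track"))
  chroms <- unique(track$probes$chrom)
  if (is.null(chrom)) {
    if (length(chroms) > 1) stop("multiple chromosomes; supply `chrom`")
    chrom <- chroms
  }
  p <- track$probes[track$probes$chrom == chrom, , drop = FALSE]
  if (nrow(p) < 2) stop("need >= 2 probes to interpolate")
  lo <- ceiling(min(p$pos)); hi <- floor(max(p$pos))
  if (!is.null(from)) lo <- max(lo, from)
  if (!is.null(to)) hi <- min(hi, to)
  if (lo > hi) stop("requested span outside probe coverage")
  f <- stats::splinefun(p$pos, p$value, method = "natural")
  x <- seq.int(lo, hi)
  structure(list(chrom = chrom, start = lo, values = f(x),
                 experiment_id = track$experiment_id),
            class = "signal_track")
}

#' Interpolate all chromosomes of a track
#' @param track a [probe_track()].
#' @return named list of `signal_track`s, one per chromosome.
#' @export
interpolate_all <- function(track) {
  chroms <- unique(track$probes$chrom)
  setNames(lapply(chroms, function(ch) interpolate_to_bp(track, ch)), chroms)
}

#' Greedy extraction of 1 bp peaks with a masking window
#'
#' Iteratively takes the global argmax of the unmasked per-bp signal, emits
#' a 1 bp peak there, and masks the window of `mask_window_bp` centered on
#' it (plus/minus half the window, endpoints inclusive). Stops when
#' everything is masked, `max_peaks` is reached, or the remaining maximum
#' falls below `floor`. Ties at the argmax break to the leftmost coordinate,
#' then to the lexicographically first chromosome.
#'
#' @param signal a `signal_track` or a list of them (one per chromosome).
#' @param mask_window_bp total mask width in bp (default 600).
#' @param max_peaks optional cap on the number of peaks.
#' @param floor stop once the unmasked maximum is below this value
#'   (default `-Inf`; the pipeline wrapper passes the raw track mean).
#' @return data.frame `(chrom, pos, height, rank)` in extraction
#'   (non-increasing height) order.
#' @export
extract_peaks <- function(signal, mask_window_bp = 600, max_peaks = NULL,
                          floor = -Inf) {
  if (inherits(signal, "signal_track")) signal <- list(signal)
  if (length(signal) == 0) stop("empty signal")
  half <- mask_window_bp %/% 2
  per_chrom <- lapply(signal, function(s) {
    v <- s$values
    n <- length(v)
    if (n == 0) return(NULL)
    pos <- integer(0); height <- numeric(0)
    repeat {
      m <- which.max(v)
      h <- v[m]
      if (!is.finite(h) || h < floor) break
      pos <- c(pos, s$start + m - 1L)
      height <- c(height, h)
      v[max(1L, m - half):min(n, m + half)] <- -Inf
      if (!is.null(max_peaks) && length(pos) >= max_peaks) break
    }
    if (length(pos) == 0) return(NULL)
    data.frame(chrom = s$chrom, pos = pos, height = height,
               stringsAsFactors = FALSE)
  })
  peaks <- do.call(rbind, per_chrom)
  if (is.null(peaks) || nrow(peaks) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      height = numeric(0), rank = integer(0)))
  }
  peaks <- peaks[order(-peaks$height, peaks$pos, peaks$chrom), , drop = FALSE]
  if (!is.null(max_peaks)) peaks <- head(peaks, max_peaks)
  peaks$rank <- seq_len(nrow(peaks))
  rownames(peaks) <- NULL
  peaks
}

#' Z-score significance calling of extracted peaks
#'
#' Retains peaks whose height exceeds the experiment's raw probe mean by at
#' least `z` raw standard deviations: `height >= mean_raw + z * sd_raw`.
#' The reference distribution is the raw (pre-blur) probe log2 values of the
#' same experiment.
#'
#' @param peaks data.frame from [extract_peaks()].
#' @param track_stats a [probe_track()] or a list/vector with `mean_raw`
#'   and `sd_raw`.
#' @param z Z-score threshold (default 2.0).
#' @return the retained peaks with a `zscore` column.
#' @export
call_significant_peaks <- function(peaks, track_stats, z = 2.0) {
  mean_raw <- track_stats[["mean_raw"]]
  sd_raw <- track_stats[["sd_raw"]]
  if (is.null(mean_raw) || is.null(sd_raw)) {
    stop("track_stats must provide mean_raw and sd_raw")
  }
  if (sd_raw <= 0) stop("degenerate experiment: sd_raw must be > 0")
  peaks$zscore <- (peaks$height - mean_raw) / sd_raw
  out <- peaks[peaks$zscore >= z, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign significant peaks to target genes via intergenic promoters
#'
#' Each peak is mapped to the intergenic region containing it; the regulon's
#' target genes are the union of the regions' `promoter_of` sets. Peaks not
#' in any intergenic region are flagged `intragenic` and contribute no
#' targets. A peak in a convergent (non-promoter) region contributes no
#' target either, since such regions have an empty `promoter_of`.
#'
#' @param peaks significant peaks (see [call_significant_peaks()]).
#' @param regions intergenic regions from [compute_intergenic_regions()].
#' @param genes gene annotation table (used to flag intragenic peaks).
#' @param tf_id,species_id labels stored on the regulon.
#' @return an object of class `regulon`: list with `tf_id`, `species_id`,
#'   `targets` (character) and `peaks` (the input plus `region_id`,
#'   `intragenic`).
#' @export
assign_targets <- function(peaks, regions, genes = NULL, tf_id = "tf",
                           species_id = "sp") {
  region_id <- rep(NA_character_, nrow(peaks))
  intragenic <- rep(FALSE, nrow(peaks))
  targets <- character(0)
  if (nrow(peaks) > 0) {
    for (i in seq_len(nrow(peaks))) {
      hit <- which(regions$chrom == peaks$chrom[i] &
                     regions$start <= peaks$pos[i] &
                     peaks$pos[i] < regions$end)
      if (length(hit) > 0) {
        region_id[i] <- regions$region_id[hit[1]]
        targets <- union(targets, regions$promoter_of[[hit[1]]])
      } else if (!is.null(genes)) {
        intragenic[i] <- any(genes$chrom == peaks$chrom[i] &
                               genes$start <= peaks$pos[i] &
                               peaks$pos[i] < genes$end)
      }
    }
  }
  peaks$region_id <- region_id
  peaks$intragenic <- intragenic
  structure(list(tf_id = tf_id, species_id = species_id,
                 targets = sort(targets), peaks = peaks),
            class = "regulon")
}

#' @export
print.regulon <- function(x, ...) {
  cat(sprintf("regulon %s (%s): %d target genes from %d peak(s)\n",
              x$tf_id, x$species_id, length(x$targets), nrow(x$peaks)))
  invisible(x)
}

#' Full peak-calling pipeline for one experiment
#'
#' Blur, interpolate each chromosome to 1 bp, greedily extract peaks (floor
#' at the raw track mean), call significance at `z`, and assign promoter
#' targets.
#'
#' @param track a [probe_track()].
#' @param regions intergenic regions.
#' @param genes gene annotations.
#' @param sigma_bp blur kernel sd (bp).
#' @param mask_window_bp mask width (bp).
#' @param z Z-score threshold.
#' @param tf_id label; defaults to the track's experiment id.
#' @return a `regulon`.
#' @export
call_regulon <- function(track, regions, genes, sigma_bp = 50,
                         mask_window_bp = 600, z = 2.0,
                         tf_id = track$experiment_id) {
  blurred <- gaussian_blur(track, sigma_bp)
  signals <- interpolate_all(blurred)
  peaks <- extract_peaks(signals, mask_window_bp = mask_window_bp,
                         floor = track$mean_raw)
  sig <- call_significant_peaks(peaks, track, z = z)
  assign_targets(sig, regions, genes, tf_id = tf_id,
                 species_id = track$species_id)
}

#' ORF-level differential signal between two tracks
#'
#' For two experiments on the same probe grid (e.g. a histone-acetylation
#' ChIP before and after rapamycin), computes the per-ORF mean of probewise
#' log2 differences (`a - b`) over probes inside each ORF span, then flags
#' ORFs whose mean lies at least `z` scale units below the center of the
#' per-ORF distribution (one-sided "decrease" rule). By default center and
#' scale are the median and the MAD, so the truly decreased ORFs do not
#' inflate the reference distribution they are tested against;
#' `location = "mean"` uses mean and standard deviation instead. The
#' fraction of significant ORFs flagged ribosomal-protein is attached as
#' attribute `rp_fraction`.
#'
#' @param track_a,track_b [probe_track()]s on identical probe grids.
#' @param genes gene annotation table (columns `gene_id`, `chrom`, `start`,
#'   `end`, `is_rp`).
#' @param z one-sided Z threshold (default 2.0).
#' @param location `"median"` (default; MAD scale) or `"mean"` (sd scale).
#' @return data.frame `(gene_id, n_probes, mean_diff, zscore, significant,
#'   is_rp)`; ORFs with no probes are excluded with a message. When the
#'   scale is zero (e.g. identical tracks) nothing is significant.
#' @export
differential_orf_signal <- function(track_a, track_b, genes, z = 2.0,
                                    location = c("median", "mean")) {
  location <- match.arg(location)
  pa <- track_a$probes; pb <- track_b$probes
  if (nrow(pa) != nrow(pb) || any(pa$chrom != pb$chrom) ||
      any(pa$pos != pb$pos)) {
    stop("tracks are not on the same probe grid")
  }
  d <- pa$value - pb$value
  res <- lapply(seq_len(nrow(genes)), function(i) {
    sel <- pa$chrom == genes$chrom[i] & pa$pos >= genes$start[i] &
      pa$pos < genes$end[i]
    n <- sum(sel)
    data.frame(gene_id = genes$gene_id[i], n_probes = n,
               mean_diff = if (n > 0) mean(d[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  dropped <- sum(res$n_probes == 0)
  if (dropped > 0) message(dropped, " ORF(s) with no probes excluded")
  res <- res[res$n_probes > 0, , drop = FALSE]
  if (location == "median") {
    gm <- stats::median(res$mean_diff)
    gs <- stats::mad(res$mean_diff)
  } else {
    gm <- mean(res$mean_diff)
    gs <- stats::sd(res$mean_diff)
  }
  res$zscore <- if (gs > 0) (res$mean_diff - gm) / gs else 0
  res$significant <- gs > 0 & res$mean_diff <= gm - z * gs
  res$is_rp <- if ("is_rp" %in% names(genes)) {
    genes$is_rp[match(res$gene_id, genes$gene_id)]
  } else FALSE
  rownames(res) <- NULL
  attr(res, "rp_fraction") <- if (any(res$significant)) {
    mean(res$is_rp[res$significant])
  } else NA_real_
  res
}

#' Write peaks as BED6
#'
#' One 1 bp interval per peak; `name` is the experiment id, `score` is
#' `round(100 * zscore)`.
#'
#' @param regulon a `regulon` (or a peaks data.frame with a `zscore`
#'   column plus `experiment` argument).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(regulon, path) {
  pk <- regulon$peaks
  df <- data.frame(chrom = pk$chrom, start = pk$pos, end = pk$pos + 1L,
                   name = regulon$tf_id,
                   score = as.integer(round(100 * pk$zscore)),
                   strand = ".")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
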
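# Pairwise TF co-occupancy over promoter regions (normalized scalar
# product of per-bp signals), reference-anchored peak distances, and the
# distance-weighted association graph.

#' Per-region 1 bp signals for co-occupancy analysis
#'
#' Interpolates one experiment's track to every base pair of each region.
#' Regions extending beyond the probe coverage are clipped (all tracks on
#' the same array grid clip identically, keeping spans comparable).
#'
#' @param track a [probe_track()].
#' @param regions region table (`region_id`, `chrom`, `start`, `end`).
#' @param sigma_bp optional blur applied before interpolation (0 = none).
#' @return named list mapping `region_id` to a numeric per-bp vector.
#' @export
region_signals <- function(track, regions, sigma_bp = 0) {
  if (sigma_bp > 0) track <- gaussian_blur(track, sigma_bp)
  out <- list()
  for (i in seq_len(nrow(regions))) {
    out[[regions$region_id[i]]] <-
      interpolate_to_bp(track, regions$chrom[i], from = regions$start[i],
                        to = regions$end[i] - 1)$values
  }
  out
}

#' Pairwise TF co-occupancy matrix
#'
#' For every region and TF pair the score is the normalized scalar product
#' (cosine) of the two per-bp signal vectors,
#' `sum(a*b) / sqrt(sum(a^2) * sum(b^2))` (0 when either norm is 0); the
#' matrix entry is the unweighted mean over regions. `"pearson"` centers
#' each vector first; `"raw"` uses the unnormalized dot product.
#'
#' @param signals named list per TF of [region_signals()] output; all TFs
#'   must cover identical region spans.
#' @param method `"cosine"` (default), `"pearson"` or `"raw"`.
#' @return an object of class `cooccupancy_matrix`: list with `matrix`
#'   (TF x TF), `per_region` (data.frame `region_id, tf1, tf2, score`) and
#'   `method`.
#' @export
cooccupancy_matrix <- function(signals,
                               method = c("cosine", "pearson", "raw")) {
  method <- match.arg(method)
  tfs <- names(signals)
  stopifnot(length(tfs) >= 2)
  regions <- names(signals[[1]])
  for (tf in tfs) {
    if (!identical(names(signals[[tf]]), regions) ||
        !identical(lengths(signals[[tf]]), lengths(signals[[1]]))) {
      stop("mismatched region spans between tracks")
    }
  }
  score1 <- function(a, b) {
    if (method == "pearson") { a <- a - mean(a); b <- b - mean(b) }
    s <- sum(a * b)
    if (method == "raw") return(s)
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    s / (na * nb)
  }
  per <- list()
  m <- matrix(NA_real_, length(tfs), length(tfs),
              dimnames = list(tfs, tfs))
  for (i in seq_along(tfs)) {
    for (j in seq_along(tfs)) {
      if (j < i) { m[i, j] <- m[j, i]; next }
      sc <- vapply(regions, function(r) {
        score1(signals[[i]][[r]], signals[[j]][[r]])
      }, numeric(1))
      m[i, j] <- mean(sc)
      if (j > i) {
        per[[length(per) + 1]] <- data.frame(
          region_id = regions, tf1 = tfs[i], tf2 = tfs[j], score = sc,
          stringsAsFactors = FALSE)
      }
    }
  }
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  structure(list(matrix = m, per_region = per, method = method),
            class = "cooccupancy_matrix")
}

#' @export
print.cooccupancy_matrix <- function(x, ...) {
  cat(sprintf("cooccupancy_matrix (%s) over %d region(s):\n", x$method,
              length(unique(x$per_region$region_id))))
  print(round(x$matrix, 3))
  invisible(x)
}

#' Distances between a reference TF's maximum peak and another TF's peaks
#'
#' Per region where both TFs have at least one peak: the reference anchor
#' is the reference TF's highest peak in the region, the distance is to the
#' other TF's nearest peak. Mean and sample sd (n - 1) are taken over
#' regions.
#'
#' @param ref_peaks,other_peaks peak data.frames carrying `region_id`,
#'   `pos`, `height` (e.g. `regulon$peaks`).
#' @param ref_tf,other_tf labels.
#' @return list with `ref_tf`, `other_tf`, `distances` (data.frame
#'   `region_id, distance`), `mean`, `sd`, `n_regions`.
#' @export
peak_distance_summary <- function(ref_peaks, other_peaks, ref_tf = "ref",
                                  other_tf = "other") {
  if (inherits(ref_peaks, "regulon")) ref_peaks <- ref_peaks$peaks
  if (inherits(other_peaks, "regulon")) other_peaks <- other_peaks$peaks
  shared <- intersect(stats::na.omit(ref_peaks$region_id),
                      stats::na.omit(other_peaks$region_id))
  if (length(shared) == 0) stop("no regions shared between the two TFs")
  dist <- vapply(shared, function(r) {
    rp <- ref_peaks[ref_peaks$region_id %in% r, , drop = FALSE]
    anchor <- rp$pos[which.max(rp$height)]
    op <- other_peaks[other_peaks$region_id %in% r, , drop = FALSE]
    min(abs(op$pos - anchor))
  }, numeric(1))
  list(ref_tf = ref_tf, other_tf = other_tf,
       distances = data.frame(region_id = shared, distance = dist,
                              row.names = NULL),
       mean = mean(dist),
       sd = if (length(dist) > 1) stats::sd(dist) else 0,
       n_regions = length(dist))
}

#' Distance-weighted TF association graph
#'
#' Undirected graph over TFs whose edges carry the mean reference-anchored
#' peak distance (`length` attribute) and the co-occupancy score
#' (`weight` attribute). Pairs without a distance summary or co-occupancy
#' entry are omitted with a message.
#'
#' @param distance_summaries list of [peak_distance_summary()] results.
#' @param cooccupancy a [cooccupancy_matrix()].
#' @return an undirected `igraph`.
#' @export
distance_covariance_graph <- function(distance_summaries, cooccupancy) {
  m <- cooccupancy$matrix
  tfs <- rownames(m)
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(tfs), name = tfs)
  for (ds in distance_summaries) {
    a <- ds$ref_tf; b <- ds$other_tf
    if (!a %in% tfs || !b %in% tfs) {
      message("skipping pair ", a, "-", b, ": no co-occupancy entry")
      next
    }
    g <- igraph::add_edges(g, match(c(a, b), tfs),
                           weight = m[a, b], length = ds$mean)
  }
  wanted <- utils::combn(tfs, 2)
  have <- igraph::as_edgelist(g)
  for (i in seq_len(ncol(wanted))) {
    pr <- wanted[, i]
    if (!any((have[, 1] == pr[1] & have[, 2] == pr[2]) |
             (have[, 1] == pr[2] & have[, 2] == pr[1]))) {
      message("pair ", pr[1], "-", pr[2], " has no distance summary; ",
              "edge omitted")
    }
  }
  g
}
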
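# Regulon statistics: hypergeometric enrichment, cross-species overlap
# under orthology, genome coverage, GO enrichment, randomized nulls with
# optional promoter-length weighting, TF-centred network construction and
# conserved-edge counting.

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of at
#' least `k` successes when drawing `n` items without replacement from a
#' universe of `N` containing `K` successes. This is the enrichment
#' statistic used throughout the pipeline.
#'
#' @param k observed overlap count.
#' @param K number of successes in the universe (category size).
#' @param n number of draws (query size).
#' @param N universe size.
#' @return the tail probability, in (0, 1]; `k = 0` gives exactly 1.
#' @examples
#' hypergeometric_tail(5, 5, 5, 10)  # 1/252
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  if (any(N < 0) || any(K < 0) || any(n < 0) || any(K > N) || any(n > N)) {
    stop("require 0 <= K, n <= N")
  }
  if (any(k < 0) || any(k > pmin(n, K))) {
    stop("require 0 <= k <= min(n, K)")
  }
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Overlap between two regulons
#'
#' In `cross_species` mode the universe is the set of ortholog *pairs*:
#' each pair is one trial, `n` and `K` are the numbers of pairs whose
#' species-1 (resp. species-2) member is bound, and `k` the pairs bound in
#' both species. Many-to-many orthology is counted at the pair level. In
#' `within_species` mode plain gene sets are intersected over a supplied
#' universe.
#'
#' @param regulon_a,regulon_b `regulon` objects or character vectors of
#'   target gene ids (species 1 and species 2 in cross-species mode).
#' @param orthology an [orthology_map()] (cross-species mode).
#' @param universe character vector of gene ids (within-species mode).
#' @param mode `"cross_species"` or `"within_species"`.
#' @param ns_threshold overlaps with `p` above this are labelled
#'   non-significant (default 1e-2).
#' @return one-row data.frame `(k, n, K, N, p, significant)`.
#' @export
regulon_overlap <- function(regulon_a, regulon_b, orthology = NULL,
                            universe = NULL,
                            mode = c("cross_species", "within_species"),
                            ns_threshold = 1e-2) {
  mode <- match.arg(mode)
  a <- if (inherits(regulon_a, "regulon")) regulon_a$targets else regulon_a
  b <- if (inherits(regulon_b, "regulon")) regulon_b$targets else regulon_b
  if (mode == "cross_species") {
    if (is.null(orthology) || nrow(orthology$pairs) == 0) {
      stop("cross-species overlap requires a non-empty orthology map")
    }
    in_a <- orthology$pairs$gene1 %in% a
    in_b <- orthology$pairs$gene2 %in% b
    k <- sum(in_a & in_b); n <- sum(in_a); K <- sum(in_b)
    N <- nrow(orthology$pairs)
  } else {
    if (is.null(universe) || length(universe) == 0) {
      stop("within-species overlap requires a universe")
    }
    a <- intersect(a, universe); b <- intersect(b, universe)
    k <- length(intersect(a, b)); n <- length(a); K <- length(b)
    N <- length(universe)
  }
  p <- hypergeometric_tail(k, K, n, N)
  data.frame(k = k, n = n, K = K, N = N, p = p,
             significant = p <= ns_threshold)
}

#' Genome coverage of a regulon
#'
#' Percentage of the gene (or intergenic-region) universe bound by a TF.
#'
#' @param regulon a `regulon` or character vector of targets.
#' @param universe character vector of all genes (or region ids).
#' @return percentage in \[0, 100\].
#' @export
genome_coverage <- function(regulon, universe) {
  t <- if (inherits(regulon, "regulon")) regulon$targets else regulon
  if (length(universe) == 0) stop("empty universe")
  100 * length(intersect(t, universe)) / length(universe)
}

#' GO enrichment of a target gene set
#'
#' One hypergeometric tail test per GO term with at least one universe gene,
#' on expanded annotations. No multiple-testing correction is applied to the
#' reported `p` (matching the raw display thresholds used downstream); a
#' Bonferroni column over the tested terms is reported alongside.
#'
#' @param targets character vector of target gene ids (must lie in
#'   `universe`).
#' @param go an expanded [go_annotation_set()].
#' @param universe character vector of all genes under consideration.
#' @param p_display display threshold for network edges (default 1e-2).
#' @param p_strict strict significance threshold (default 1e-4).
#' @return data.frame `(term, k, n, K, N, p, p_bonferroni, display,
#'   strict)`, sorted by ascending `p`.
#' @export
go_enrichment <- function(targets, go, universe, p_display = 1e-2,
                          p_strict = 1e-4) {
  stopifnot(inherits(go, "go_annotation_set"))
  if (!go$expanded) {
    stop("annotations must be expanded first (expand_go_annotations)")
  }
  if (!all(targets %in% universe)) {
    stop("targets must be a subset of the universe")
  }
  targets <- unique(targets)
  N <- length(universe)
  n <- length(targets)
  rows <- lapply(names(go$terms), function(tm) {
    cat_genes <- intersect(go$terms[[tm]], universe)
    K <- length(cat_genes)
    if (K == 0) return(NULL)
    k <- length(intersect(targets, cat_genes))
    data.frame(term = tm, k = k, n = n, K = K, N = N,
               p = hypergeometric_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      p_bonferroni = numeric(0), display = logical(0),
                      strict = logical(0)))
  }
  res$p_bonferroni <- pmin(1, res$p * nrow(res))
  res$display <- res$p < p_display
  res$strict <- res$p < p_strict
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Randomized pseudo-regulon null distribution
#'
#' Draws `n_draws` pseudo-regulons of `regulon_size` promoters, either
#' uniformly or with probability proportional to promoter length (the
#' promoter-length correction: long promoters accumulate noise peaks and
#' should be sampled accordingly in the null), and applies a caller-supplied
#' statistic to each draw.
#'
#' @param regulon_size number of promoters per draw.
#' @param promoters data.frame with columns `region_id`, `length`.
#' @param statistic function taking a character vector of sampled region
#'   ids, returning one number.
#' @param weight_by_length sample proportional to length? (default FALSE).
#' @param n_draws number of draws (warning below 100).
#' @param seed RNG seed (draws are reproducible given the seed).
#' @return numeric vector of `n_draws` statistic values.
#' @export
randomized_target_null <- function(regulon_size, promoters, statistic,
                                   weight_by_length = FALSE,
                                   n_draws = 1000, seed = 1) {
  stopifnot(regulon_size <= nrow(promoters))
  if (n_draws < 100) warning("n_draws < 100: null will be coarse")
  prob <- if (weight_by_length) promoters$length else NULL
  withr::with_seed(seed, {
    vapply(seq_len(n_draws), function(i) {
      ids <- sample(promoters$region_id, regulon_size, replace = FALSE,
                    prob = prob)
      statistic(ids)
    }, numeric(1))
  })
}

#' Build a TF-centred network
#'
#' Three modes. `tf_go`: a directed edge from each TF to every GO term
#' passing the display threshold in its enrichment results (edge weight
#' `-log10(p)`). `tf_tf`: an edge TFa -> TFb whenever TFb's gene is a
#' target of TFa's regulon; binding one's own promoter yields a self-loop
#' (auto-regulation). `tf_kinase`: analogous, from TFs to kinase genes.
#' For cross-species comparison the caller restricts `node_genes` to the
#' shared-ortholog set beforehand.
#'
#' @param regulons named list of `regulon` objects (names = TF node ids).
#' @param mode `"tf_go"`, `"tf_tf"` or `"tf_kinase"`.
#' @param go_results for `tf_go`: named list (per TF) of [go_enrichment()]
#'   tables.
#' @param node_genes for `tf_tf`/`tf_kinase`: data.frame with columns
#'   `node_id` (TF or kinase label) and `gene_id` (its gene in this
#'   species).
#' @param species species label stored as a graph attribute.
#' @return a directed `igraph` with vertex attribute `type` and edge
#'   attribute `weight`.
#' @export
build_network <- function(regulons, mode = c("tf_go", "tf_tf", "tf_kinase"),
                          go_results = NULL, node_genes = NULL,
                          species = NA_character_) {
  mode <- match.arg(mode)
  tfs <- names(regulons)
  edges <- character(0)
  weights <- numeric(0)
  if (mode == "tf_go") {
    if (is.null(go_results)) stop("tf_go mode needs go_results")
    terms <- character(0)
    for (tf in tfs) {
      res <- go_results[[tf]]
      hit <- res[res$display, , drop = FALSE]
      terms <- union(terms, hit$term)
      if (nrow(hit) > 0) {
        edges <- c(edges, rbind(tf, hit$term))
        weights <- c(weights, -log10(hit$p))
      }
    }
    vnames <- c(tfs, terms)
    vtype <- c(rep("TF", length(tfs)), rep("GO", length(terms)))
  } else {
    if (is.null(node_genes)) stop(mode, " mode needs node_genes")
    target_type <- if (mode == "tf_tf") "TF" else "kinase"
    for (tf in tfs) {
      tg <- regulons[[tf]]$targets
      hit <- node_genes[node_genes$gene_id %in% tg, , drop = FALSE]
      if (nrow(hit) > 0) {
        edges <- c(edges, rbind(tf, hit$node_id))
        weights <- c(weights, rep(1, nrow(hit)))
      }
    }
    vnames <- union(tfs, node_genes$node_id)
    vtype <- ifelse(vnames %in% tfs, "TF", target_type)
  }
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(g, length(vnames), name = vnames, type = vtype)
  if (length(edges) > 0) {
    g <- igraph::add_edges(g, match(edges, vnames), weight = weights)
  }
  igraph::graph_attr(g, "species") <- species
  g
}

#' Count conserved edges between two species' networks
#'
#' An edge `u -> v` of network A is conserved when some ortholog pair
#' `(u, u')` and `(v, v')` yields the edge `u' -> v'` in network B (self
#' pairs via `node_map` identify TF node labels across species when node
#' ids are shared). The total is the union of edges under ortholog
#' identification: edges of A plus B edges matched to no A edge.
#'
#' @param network_a,network_b directed `igraph`s whose vertex names are
#'   gene ids (or shared node labels).
#' @param orthology an [orthology_map()] mapping A-side names to B-side
#'   names; identical names are always considered orthologous.
#' @return list with `n_conserved`, `n_total` and `conserved` (data.frame
#'   of conserved A edges).
#' @export
conserved_edges <- function(network_a, network_b, orthology) {
  ea <- igraph::as_edgelist(network_a, names = TRUE)
  eb <- igraph::as_edgelist(network_b, names = TRUE)
  pairs <- orthology$pairs
  maps_to <- function(u) unique(c(u, pairs$gene2[pairs$gene1 == u]))
  eb_keys <- if (nrow(eb) > 0) paste(eb[, 1], eb[, 2], sep = "\r") else
    character(0)
  conserved <- logical(nrow(ea))
  matched_b <- rep(FALSE, nrow(eb))
  if (nrow(ea) > 0) {
    for (i in seq_len(nrow(ea))) {
      cand <- as.vector(outer(maps_to(ea[i, 1]), maps_to(ea[i, 2]),
                              paste, sep = "\r"))
      hit <- eb_keys %in% cand
      if (any(hit)) {
        conserved[i] <- TRUE
        matched_b <- matched_b | hit
      }
    }
  }
  n_total <- nrow(ea) + sum(!matched_b)
  list(n_conserved = sum(conserved), n_total = n_total,
       conserved = if (nrow(ea) > 0) {
         data.frame(from = ea[conserved, 1], to = ea[conserved, 2],
                    stringsAsFactors = FALSE)
       } else data.frame(from = character(0), to = character(0)))
}

#' Write an enrichment table as TSV
#' @param results data.frame (e.g. from [go_enrichment()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_tsv <- function(results, path) {
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
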
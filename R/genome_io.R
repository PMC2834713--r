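# Data model and readers/writers: gene annotations, intergenic regions,
# probe tracks, orthology tables, GO annotation sets, Pajek network files.
# All internal coordinates are 0-based half-open; conversions happen only at
# the I/O boundary (GFF3 is 1-based inclusive, BED already 0-based half-open).

#' Read gene annotations from GFF3 or BED
#'
#' Parses a GFF3 or BED file into the package's internal annotation table.
#' Internal coordinates are 0-based half-open regardless of the source
#' dialect. Optional gene lists flag ribosomal-protein (RP), transcription
#' factor (TF) and kinase genes.
#'
#' @param path path to a GFF3 or BED file.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @param rp_genes,tf_genes,kinase_genes optional character vectors of gene
#'   ids, or paths to one-id-per-line files.
#' @param feature_type for GFF3, keep only features of this type (default
#'   `"gene"`; ignored when the file carries no type column).
#' @return a `data.frame` with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `is_rp`, `is_tf`, `is_kinase`.
#' @examples
#' gff <- tempfile(fileext = ".gff3")
#' writeLines(c("##gff-version 3",
#'   "chr1\tsrc\tgene\t11\t20\t.\t+\t.\tID=g1"), gff)
#' read_gene_annotations(gff)  # start 10, end 20 internally
#' @export
read_gene_annotations <- function(path, format = c("auto", "gff3", "bed"),
                                  rp_genes = NULL, tf_genes = NULL,
                                  kinase_genes = NULL,
                                  feature_type = "gene") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed"),
    error = function(e) stop("failed to parse ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(gr) == 0) {
    warning("no annotations in ", path)
    return(empty_gene_annotations())
  }
  meta <- S4Vectors::mcols(gr)
  if (format == "gff3" && "type" %in% colnames(meta) &&
      any(as.character(meta$type) == feature_type)) {
    gr <- gr[as.character(meta$type) == feature_type]
    meta <- S4Vectors::mcols(gr)
  }
  ids <- NULL
  for (col in c("ID", "Name", "name", "gene_id")) {
    if (col %in% colnames(meta) && !all(is.na(meta[[col]]))) {
      ids <- as.character(meta[[col]])
      break
    }
  }
  if (is.null(ids)) ids <- paste0("feature_", seq_along(gr))
  if (anyDuplicated(ids)) {
    stop("duplicate gene_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  # rtracklayer yields 1-based inclusive starts for both dialects.
  ann <- data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  if (any(ann$start >= ann$end)) {
    bad <- which(ann$start >= ann$end)[1]
    stop("invalid coordinates for gene ", ann$gene_id[bad])
  }
  rp <- as_gene_list(rp_genes); tf <- as_gene_list(tf_genes)
  kin <- as_gene_list(kinase_genes)
  ann$is_rp <- ann$gene_id %in% rp
  ann$is_tf <- ann$gene_id %in% tf
  ann$is_kinase <- ann$gene_id %in% kin
  ann
}

empty_gene_annotations <- function() {
  data.frame(gene_id = character(0), chrom = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             is_rp = logical(0), is_tf = logical(0), is_kinase = logical(0),
             stringsAsFactors = FALSE)
}

#' Write gene annotations as GFF3 or BED
#'
#' Inverse of [read_gene_annotations()]; internal 0-based half-open
#' coordinates are converted back to the target dialect.
#'
#' @param genes annotation table as returned by [read_gene_annotations()].
#' @param path output path.
#' @param format `"gff3"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_gene_annotations <- function(genes, path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  if (format == "gff3") {
    gr$type <- "gene"
    gr$ID <- genes$gene_id
    gr$source <- "regrewire"
  } else {
    gr$name <- genes$gene_id
    gr$score <- 0L
  }
  rtracklayer::export(gr, path, format = format)
  invisible(path)
}

#' Derive intergenic regions and their promoter assignments
#'
#' Gene spans are merged per chromosome (overlapping genes collapse into one
#' span) and the maximal gaps between spans, plus chromosome-end gaps, become
#' intergenic regions. A region is the promoter of each flanking gene that is
#' transcribed away from it: the downstream (right) gene when on `+`, the
#' upstream (left) gene when on `-`. Divergent flanks give two promoter
#' genes, convergent flanks none.
#'
#' @param genes gene annotation table (see [read_gene_annotations()]).
#' @param chrom_sizes named numeric vector, data.frame or two-column TSV of
#'   chromosome sizes.
#' @return a `data.frame` with columns `region_id`, `chrom`, `start`, `end`,
#'   `left_gene`, `right_gene` (NA at chromosome ends) and a list-column
#'   `promoter_of`.
#' @export
compute_intergenic_regions <- function(genes, chrom_sizes) {
  chrom_sizes <- as_chrom_sizes(chrom_sizes)
  out <- list()
  for (chr in names(chrom_sizes)) {
    size <- chrom_sizes[[chr]]
    g <- genes[genes$chrom == chr, , drop = FALSE]
    if (nrow(g) > 0 && any(g$end > size | g$start < 0)) {
      stop("gene outside chromosome ", chr)
    }
    if (nrow(g) == 0) {
      out[[chr]] <- data.frame(chrom = chr, start = 0, end = size,
                               left_gene = NA_character_,
                               right_gene = NA_character_,
                               stringsAsFactors = FALSE)
      out[[chr]]$promoter_of <- list(character(0))
      next
    }
    spans <- IRanges::reduce(IRanges::IRanges(start = g$start + 1L,
                                              end = g$end))
    gaps <- IRanges::gaps(spans, start = 1L, end = as.integer(size))
    if (length(gaps) == 0) next
    gs <- IRanges::start(gaps) - 1L  # back to 0-based half-open
    ge <- IRanges::end(gaps)
    left <- right <- rep(NA_character_, length(gaps))
    prom <- vector("list", length(gaps))
    for (i in seq_along(gaps)) {
      p <- character(0)
      li <- which(g$end == gs[i])
      if (length(li) > 0) {
        li <- li[which.max(g$end[li])]
        left[i] <- g$gene_id[li]
        if (g$strand[li] == "-") p <- c(p, g$gene_id[li])
      }
      ri <- which(g$start == ge[i])
      if (length(ri) > 0) {
        ri <- ri[which.min(g$start[ri])]
        right[i] <- g$gene_id[ri]
        if (g$strand[ri] == "+") p <- c(p, g$gene_id[ri])
      }
      prom[[i]] <- p
    }
    df <- data.frame(chrom = chr, start = gs, end = ge, left_gene = left,
                     right_gene = right, stringsAsFactors = FALSE)
    df$promoter_of <- prom
    out[[chr]] <- df
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0) return(res)
  res$region_id <- sprintf("%s_ig%04d", res$chrom,
                           stats::ave(seq_len(nrow(res)), res$chrom,
                                      FUN = seq_along))
  rownames(res) <- NULL
  res[, c("region_id", "chrom", "start", "end", "left_gene", "right_gene",
          "promoter_of")]
}

#' Construct a probe track
#'
#' A probe track stores, for one ChIP-chip experiment, the sorted probe
#' positions and log2 IP/control enrichment ratios, together with the mean
#' and standard deviation of the raw probe distribution (the reference for
#' Z-score peak calling, computed over all probes of the experiment).
#'
#' @param probes data.frame with columns `chrom`, `pos`, `value`.
#' @param experiment_id,species_id identifier strings.
#' @return an object of class `probe_track`.
#' @export
probe_track <- function(probes, experiment_id = "exp", species_id = "sp") {
  stopifnot(all(c("chrom", "pos", "value") %in% names(probes)))
  if (nrow(probes) == 0) stop("empty probe track")
  if (!is.numeric(probes$value) || anyNA(probes$value)) {
    stop("non-numeric probe value")
  }
  ord <- order(probes$chrom, probes$pos)
  if (is.unsorted(ord) && any(ord != seq_len(nrow(probes)))) {
    message("probe track not sorted; sorting")
  }
  probes <- probes[ord, , drop = FALSE]
  dup <- stats::ave(probes$pos, probes$chrom,
                    FUN = function(p) duplicated(p))
  if (any(dup == 1)) stop("duplicate probe position")
  rownames(probes) <- NULL
  structure(list(experiment_id = experiment_id, species_id = species_id,
                 probes = probes,
                 mean_raw = mean(probes$value),
                 sd_raw = stats::sd(probes$value)),
            class = "probe_track")
}

#' @export
print.probe_track <- function(x, ...) {
  cat(sprintf("probe_track '%s' (%s): %d probes on %d chromosome(s), mean_raw=%.4f sd_raw=%.4f\n",
              x$experiment_id, x$species_id, nrow(x$probes),
              length(unique(x$probes$chrom)), x$mean_raw, x$sd_raw))
  invisible(x)
}

#' Read a probe-level enrichment track
#'
#' Accepts bedGraph (4 columns, intervals represented by their midpoint
#' `floor((start + end) / 2)` in 0-based coordinates) or a TSV with columns
#' `chrom`, `pos`, `value`. Probes are sorted if needed (with a message);
#' duplicate positions are an error. `mean_raw` and `sd_raw` summarize the
#' raw probe log2 distribution of the whole experiment.
#'
#' @param path input file.
#' @param experiment_id,species_id identifier strings.
#' @param format `"auto"`, `"bedgraph"` or `"tsv"`.
#' @return a [probe_track()] object.
#' @export
read_probe_track <- function(path, experiment_id = basename(path),
                             species_id = "sp",
                             format = c("auto", "bedgraph", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(bedgraph|bg)$", path, ignore.case = TRUE))
      "bedgraph" else "tsv"
  }
  if (format == "bedgraph") {
    gr <- rtracklayer::import(path, format = "bedGraph")
    probes <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                         pos = floor((GenomicRanges::start(gr) - 1L +
                                        GenomicRanges::end(gr)) / 2),
                         value = gr$score, stringsAsFactors = FALSE)
  } else {
    probes <- read.delim(path, stringsAsFactors = FALSE)
    names(probes) <- tolower(names(probes))
    if ("position" %in% names(probes)) {
      names(probes)[names(probes) == "position"] <- "pos"
    }
    if ("log2_ratio" %in% names(probes)) {
      names(probes)[names(probes) == "log2_ratio"] <- "value"
    }
    if (!all(c("chrom", "pos", "value") %in% names(probes))) {
      stop("TSV probe track needs columns chrom, pos, value")
    }
    if (!is.numeric(probes$value)) stop("non-numeric probe value in ", path)
  }
  probe_track(probes, experiment_id = experiment_id,
              species_id = species_id)
}

#' Write a probe track as TSV
#' @param track a [probe_track()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_track <- function(track, path) {
  df <- track$probes
  df$value <- round(df$value, 6)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a GO annotation set
#'
#' @param term2gene named list mapping GO term ids to character vectors of
#'   gene ids, or a two-column data.frame `(term, gene)`.
#' @param hierarchy data.frame with columns `child`, `parent` (term ids),
#'   forming a DAG; may be empty.
#' @param expanded logical, whether annotations already include ancestors.
#' @return an object of class `go_annotation_set`.
#' @export
go_annotation_set <- function(term2gene, hierarchy = NULL, expanded = FALSE) {
  if (is.data.frame(term2gene)) {
    term2gene <- split(as.character(term2gene[[2]]),
                       as.character(term2gene[[1]]))
  }
  term2gene <- lapply(term2gene, function(g) sort(unique(as.character(g))))
  if (is.null(hierarchy)) {
    hierarchy <- data.frame(child = character(0), parent = character(0),
                            stringsAsFactors = FALSE)
  }
  names(hierarchy)[1:2] <- c("child", "parent")
  structure(list(terms = term2gene, hierarchy = hierarchy,
                 expanded = expanded),
            class = "go_annotation_set")
}

#' Expand GO annotations up the term hierarchy
#'
#' Propagates every gene annotated to a term to all ancestors of that term
#' (the true-path rule), so that enrichment of a child term is visible at the
#' parents. Idempotent; errors if the hierarchy contains a cycle.
#'
#' @param annotations a [go_annotation_set()], or the `term2gene` argument
#'   thereof.
#' @param hierarchy parent-child edges, if `annotations` does not carry them.
#' @return an expanded `go_annotation_set`.
#' @export
expand_go_annotations <- function(annotations, hierarchy = NULL) {
  if (!inherits(annotations, "go_annotation_set")) {
    annotations <- go_annotation_set(annotations, hierarchy)
  } else if (!is.null(hierarchy)) {
    annotations$hierarchy <- hierarchy
    names(annotations$hierarchy)[1:2] <- c("child", "parent")
  }
  h <- annotations$hierarchy
  terms <- unique(c(names(annotations$terms), h$child, h$parent))
  # Kahn topological sort; leftover nodes witness a cycle.
  parents_of <- split(h$parent, factor(h$child, levels = terms))
  indeg <- vapply(split(h$child, factor(h$parent, levels = terms)),
                  length, integer(1))
  queue <- terms[indeg == 0]
  seen <- character(0)
  indeg_w <- indeg
  while (length(queue) > 0) {
    t <- queue[1]; queue <- queue[-1]; seen <- c(seen, t)
    for (p in parents_of[[t]]) {
      indeg_w[p] <- indeg_w[p] - 1L
      if (indeg_w[p] == 0) queue <- c(queue, p)
    }
  }
  if (length(seen) < length(terms)) {
    cyc <- setdiff(terms, seen)
    stop("GO hierarchy contains a cycle involving: ",
         paste(cyc, collapse = " -> "))
  }
  # Children first in `seen` (edges point child -> parent), so one pass
  # pushing gene sets upward suffices.
  expanded <- annotations$terms
  for (t in terms) if (is.null(expanded[[t]])) expanded[[t]] <- character(0)
  for (t in seen) {
    for (p in parents_of[[t]]) {
      expanded[[p]] <- union(expanded[[p]], expanded[[t]])
    }
  }
  expanded <- lapply(expanded, function(g) sort(unique(g)))
  go_annotation_set(expanded, annotations$hierarchy, expanded = TRUE)
}

#' Read a GO hierarchy from a two-column TSV or a minimal OBO file
#'
#' The OBO reader handles only `id:` and `is_a:` lines, which is all the
#' expansion step needs.
#'
#' @param path input file (`.obo` triggers the OBO reader).
#' @return data.frame with columns `child`, `parent`.
#' @export
read_go_hierarchy <- function(path) {
  if (grepl("\\.obo$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    cur <- NA_character_
    child <- parent <- character(0)
    for (ln in lines) {
      if (grepl("^id:", ln)) cur <- trimws(sub("^id:", "", ln))
      if (grepl("^is_a:", ln) && !is.na(cur)) {
        p <- trimws(sub("^is_a:", "", ln))
        p <- trimws(sub("!.*$", "", p))
        child <- c(child, cur); parent <- c(parent, p)
      }
    }
    return(data.frame(child = child, parent = parent,
                      stringsAsFactors = FALSE))
  }
  h <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(child = as.character(h[[1]]), parent = as.character(h[[2]]),
             stringsAsFactors = FALSE)
}

#' Read gene-level GO annotations from a TSV
#' @param path TSV with two columns: term id, gene id (no header), or a
#'   header containing `term` and `gene` columns.
#' @return data.frame `(term, gene)` suitable for [go_annotation_set()].
#' @export
read_go_annotations <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("term", first, ignore.case = TRUE)
  a <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  if (has_header) {
    names(a) <- tolower(names(a))
    data.frame(term = a$term, gene = a$gene, stringsAsFactors = FALSE)
  } else {
    data.frame(term = as.character(a[[1]]), gene = as.character(a[[2]]),
               stringsAsFactors = FALSE)
  }
}

#' Construct an orthology map
#'
#' Many-to-many gene correspondences between two species. The universes are
#' the genes of each species with at least one ortholog.
#'
#' @param pairs data.frame with two columns: species-1 gene, species-2 gene.
#' @return an object of class `orthology_map` with elements `pairs`,
#'   `universe1`, `universe2`.
#' @export
orthology_map <- function(pairs) {
  pairs <- data.frame(gene1 = as.character(pairs[[1]]),
                      gene2 = as.character(pairs[[2]]),
                      stringsAsFactors = FALSE)
  pairs <- unique(pairs)
  structure(list(pairs = pairs,
                 universe1 = unique(pairs$gene1),
                 universe2 = unique(pairs$gene2)),
            class = "orthology_map")
}

#' @export
print.orthology_map <- function(x, ...) {
  cat(sprintf("orthology_map: %d pairs, universes %d x %d genes\n",
              nrow(x$pairs), length(x$universe1), length(x$universe2)))
  invisible(x)
}

#' Read an orthology table
#'
#' Two-column TSV of gene-id pairs (species 1, species 2). If annotation
#' tables are supplied, pairs mentioning unknown genes are dropped with a
#' warning stating the count.
#'
#' @param path TSV path (header optional).
#' @param genes1,genes2 optional gene annotation tables used to validate
#'   pair members.
#' @return an [orthology_map()].
#' @export
read_orthology <- function(path, genes1 = NULL, genes2 = NULL) {
  first <- tryCatch(readLines(path, n = 1), error = function(e) "")
  if (length(first) == 0 || !nzchar(first)) {
    return(orthology_map(data.frame(gene1 = character(0),
                                    gene2 = character(0))))
  }
  has_header <- grepl("gene|ortho", first, ignore.case = TRUE)
  p <- read.delim(path, header = has_header, stringsAsFactors = FALSE)
  pairs <- data.frame(gene1 = as.character(p[[1]]),
                      gene2 = as.character(p[[2]]),
                      stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(pairs))
  if (!is.null(genes1)) keep <- keep & pairs$gene1 %in% genes1$gene_id
  if (!is.null(genes2)) keep <- keep & pairs$gene2 %in% genes2$gene_id
  if (any(!keep)) {
    warning(sum(!keep), " orthology pair(s) dropped: gene absent from ",
            "annotation")
    pairs <- pairs[keep, , drop = FALSE]
  }
  orthology_map(pairs)
}

#' Export a network in Pajek .net format
#'
#' Writes `*Vertices N` with 1-based, insertion-ordered, quoted labels and
#' one arc (directed) or edge (undirected) line `src dst weight` per edge.
#'
#' @param network an `igraph` object; edge attribute `weight` is used when
#'   present (1 otherwise).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_pajek <- function(network, path) {
  stopifnot(inherits(network, "igraph"))
  n <- igraph::vcount(network)
  labels <- igraph::V(network)$name
  if (is.null(labels)) labels <- as.character(seq_len(n))
  lines <- sprintf("*Vertices %d", n)
  if (n > 0) {
    lines <- c(lines, sprintf("%d \"%s\"", seq_len(n), labels))
  }
  el <- igraph::as_edgelist(network, names = FALSE)
  w <- igraph::E(network)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  lines <- c(lines, if (igraph::is_directed(network)) "*Arcs" else "*Edges")
  if (nrow(el) > 0) {
    lines <- c(lines, sprintf("%d %d %s", el[, 1], el[, 2],
                              format(w, trim = TRUE, digits = 12)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a Pajek .net file
#'
#' Minimal reader for the dialect written by [export_pajek()]; used for
#' round-trip checks and re-importing exported networks.
#'
#' @param path Pajek file.
#' @return an `igraph` object with vertex names and edge `weight`s.
#' @export
read_pajek <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nv <- as.integer(sub("^\\*Vertices\\s+", "", lines[1], ignore.case = TRUE))
  labels <- character(nv)
  i <- 2
  while (i <= length(lines) && !grepl("^\\*", lines[i])) {
    m <- regmatches(lines[i],
                    regexec("^(\\d+)\\s+\"(.*)\"", lines[i]))[[1]]
    labels[as.integer(m[2])] <- m[3]
    i <- i + 1
  }
  directed <- i <= length(lines) &&
    grepl("^\\*Arcs", lines[i], ignore.case = TRUE)
  edges <- matrix(character(0), ncol = 2)
  weights <- numeric(0)
  if (i < length(lines)) {
    for (ln in lines[(i + 1):length(lines)]) {
      if (!nzchar(trimws(ln)) || grepl("^\\*", ln)) next
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      edges <- rbind(edges, labels[as.integer(f[1:2])])
      weights <- c(weights, if (length(f) >= 3) as.numeric(f[3]) else 1)
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = directed)
  g <- igraph::add_vertices(g, nv, name = labels)
  if (nrow(edges) > 0) {
    ids <- matrix(match(edges, labels), ncol = 2)
    g <- igraph::add_edges(g, as.vector(t(ids)), weight = weights)
  }
  g
}

#' Read a TF-target table and count regulon sizes
#'
#' For replication checks against published per-TF target lists: reads a
#' TSV with columns `tf`, `species`, `gene` (header required) and returns
#' the number of distinct target genes per TF and species.
#'
#' @param path TSV path.
#' @return data.frame `(tf, species, n_targets)`.
#' @export
read_target_counts <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  names(x) <- tolower(names(x))
  stopifnot(all(c("tf", "species", "gene") %in% names(x)))
  x <- unique(x[, c("tf", "species", "gene")])
  agg <- stats::aggregate(gene ~ tf + species, data = x,
                          FUN = function(g) length(unique(g)))
  names(agg)[3] <- "n_targets"
  agg[order(agg$species, agg$tf), , drop = FALSE]
}
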
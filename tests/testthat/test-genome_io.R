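# I/O layer: coordinate conventions, intergenic derivation, probe tracks,
# GO expansion, orthology, Pajek export.

test_that("GFF3 and BED coordinates map to 0-based half-open and round-trip", {
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t11\t20\t.\t+\t.\tID=g1",
               "chr1\tsrc\tgene\t31\t45\t.\t-\t.\tID=g2"), gff)
  ann <- read_gene_annotations(gff)
  expect_equal(ann$start, c(10, 30))
  expect_equal(ann$end, c(20, 45))
  expect_equal(ann$strand, c("+", "-"))

  bed <- tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20\tg1\t0\t+", bed)
  annb <- read_gene_annotations(bed)
  expect_equal(annb$start, 10)
  expect_equal(annb$end, 20)

  # round trips preserve positions exactly
  gff2 <- tempfile(fileext = ".gff3")
  write_gene_annotations(ann, gff2, "gff3")
  expect_equal(read_gene_annotations(gff2)[, c("start", "end")],
               ann[, c("start", "end")])
  bed2 <- tempfile(fileext = ".bed")
  write_gene_annotations(annb, bed2, "bed")
  expect_equal(read_gene_annotations(bed2)[, c("start", "end")],
               annb[, c("start", "end")])

  # duplicate ids rejected; empty file warns and yields an empty set
  dup <- tempfile(fileext = ".gff3")
  writeLines(c("chr1\tsrc\tgene\t1\t5\t.\t+\t.\tID=g1",
               "chr1\tsrc\tgene\t7\t9\t.\t+\t.\tID=g1"), dup)
  expect_error(read_gene_annotations(dup), "duplicate")
  empty <- tempfile(fileext = ".bed")
  file.create(empty)
  expect_warning(res <- read_gene_annotations(empty), "no annotations")
  expect_equal(nrow(res), 0)
})

test_that("intergenic regions follow the flanking-orientation promoter rule", {
  genes <- data.frame(
    gene_id = c("g1", "g2"), chrom = "chr1",
    start = c(2000, 6000), end = c(3000, 7000),
    strand = c("+", "+"), stringsAsFactors = FALSE)
  r <- compute_intergenic_regions(genes, c(chr1 = 10000))
  expect_equal(nrow(r), 3)
  expect_equal(r$start, c(0, 3000, 7000))
  expect_equal(r$end, c(2000, 6000, 10000))
  expect_equal(r$promoter_of, list("g1", "g2", character(0)))

  # divergent flanks promote both genes
  genes$strand <- c("-", "+")
  r2 <- compute_intergenic_regions(genes, c(chr1 = 10000))
  expect_setequal(r2$promoter_of[[2]], c("g1", "g2"))
  # and the first region is now no one's promoter (g1 points away from it)
  expect_equal(r2$promoter_of[[1]], character(0))

  # no genes: whole chromosome, no promoter
  r3 <- compute_intergenic_regions(genes[0, ], c(chr1 = 5000))
  expect_equal(r3$start, 0)
  expect_equal(r3$end, 5000)
  expect_equal(r3$promoter_of[[1]], character(0))

  expect_error(compute_intergenic_regions(
    transform(genes, end = c(3000, 20000)), c(chr1 = 10000)), "outside")
})

test_that("intergenic regions plus merged gene spans tile the chromosome", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 8
    st <- sort(sample(0:900, n))
    genes <- data.frame(gene_id = paste0("g", 1:n), chrom = "c",
                        start = st, end = st + sample(20:120, n),
                        strand = sample(c("+", "-"), n, TRUE),
                        stringsAsFactors = FALSE)
    size <- max(genes$end) + 50
    r <- compute_intergenic_regions(genes, c(c = size))
    merged <- IRanges::reduce(IRanges::IRanges(genes$start + 1, genes$end))
    covered <- sort(c(unlist(Map(seq, r$start + 1, r$end)),
                      unlist(Map(seq, IRanges::start(merged),
                                 IRanges::end(merged)))))
    expect_equal(covered, 1:size)  # no gap, no overlap
  }
})

test_that("probe tracks compute raw stats, sort input, reject duplicates", {
  tr <- probe_track(data.frame(chrom = "c", pos = c(10, 20, 30),
                               value = c(1, 2, 3)))
  expect_equal(tr$mean_raw, 2)
  expect_equal(tr$sd_raw, 1)  # sample sd

  expect_message(
    tr2 <- probe_track(data.frame(chrom = "c", pos = c(30, 10, 20),
                                  value = c(3, 1, 2))), "sorting")
  expect_equal(tr2$probes$pos, c(10, 20, 30))

  expect_error(probe_track(data.frame(chrom = "c", pos = c(10, 10),
                                      value = c(1, 2))), "duplicate")

  # bedGraph intervals become their midpoints
  bg <- tempfile(fileext = ".bedgraph")
  writeLines(c("c\t100\t200\t1.5", "c\t200\t300\t-0.5"), bg)
  tb <- read_probe_track(bg)
  expect_equal(tb$probes$pos, c(150, 250))
  expect_equal(tb$probes$value, c(1.5, -0.5))

  # TSV round trip
  tsv <- tempfile(fileext = ".tsv")
  write_probe_track(tr, tsv)
  expect_equal(read_probe_track(tsv)$probes$value, c(1, 2, 3))
})

test_that("GO expansion propagates to ancestors, is idempotent, rejects cycles", {
  hier <- data.frame(child = c("c", "p1", "p2", "c2"),
                     parent = c("p1", "root", "root", "p2"))
  go <- expand_go_annotations(list(c = "g1", c2 = c("g2", "g1")), hier)
  expect_true("g1" %in% go$terms$p1)
  expect_true(all(c("g1", "g2") %in% go$terms$root))
  # diamond: g1 reaches root via p1 and p2 but is counted once
  expect_equal(sum(go$terms$root == "g1"), 1)
  # idempotent
  go2 <- expand_go_annotations(go)
  expect_identical(go2$terms, go$terms)
  # monotone: term gene sets only grow
  raw <- go_annotation_set(list(c = "g1", c2 = c("g2", "g1")), hier)
  for (tm in names(raw$terms)) {
    expect_true(all(raw$terms[[tm]] %in% go$terms[[tm]]))
  }
  bad <- data.frame(child = c("a", "b"), parent = c("b", "a"))
  expect_error(expand_go_annotations(list(a = "g"), bad), "cycle")
})

test_that("orthology tables keep many-to-many pairs and derive universes", {
  f <- tempfile()
  writeLines(c("a1\tb1", "a2\tb2", "a3\tb3"), f)
  om <- read_orthology(f)
  expect_equal(nrow(om$pairs), 3)
  expect_equal(length(om$universe1), 3)
  expect_equal(length(om$universe2), 3)

  writeLines(c("a1\tb1", "a1\tb2"), f)
  expect_equal(nrow(read_orthology(f)$pairs), 2)  # many-to-many retained

  writeLines(c("a1\tb1", "aX\tb2"), f)
  g1 <- data.frame(gene_id = c("a1", "a2"))
  g2 <- data.frame(gene_id = c("b1", "b2"))
  expect_warning(om2 <- read_orthology(f, g1, g2), "dropped")
  expect_equal(nrow(om2$pairs), 1)

  empty <- tempfile(); file.create(empty)
  expect_equal(nrow(read_orthology(empty)$pairs), 0)
  expect_error(regulon_overlap("a", "b", read_orthology(empty)),
               "non-empty orthology")
})

test_that("Pajek export writes the documented dialect and round-trips", {
  g <- igraph::make_empty_graph(directed = TRUE)
  g <- igraph::add_vertices(g, 2, name = c("Rap1", "RPL12"))
  g <- igraph::add_edges(g, c(1, 2), weight = 0.5)
  f <- tempfile(fileext = ".net")
  export_pajek(g, f)
  lines <- readLines(f)
  expect_equal(lines[1], "*Vertices 2")
  expect_true('1 "Rap1"' %in% lines)
  expect_true(any(grepl("^1 2 0\\.5$", lines)))

  # empty graph: header only
  f0 <- tempfile(fileext = ".net")
  export_pajek(igraph::make_empty_graph(directed = TRUE), f0)
  expect_equal(readLines(f0), c("*Vertices 0", "*Arcs"))

  # write-then-parse reproduces the edge set and weights
  set.seed(3)
  n <- 6
  g2 <- igraph::sample_gnm(n, 8, directed = TRUE)
  igraph::V(g2)$name <- paste0("node", 1:n)
  igraph::E(g2)$weight <- round(runif(8), 3)
  f2 <- tempfile(fileext = ".net")
  export_pajek(g2, f2)
  back <- read_pajek(f2)
  el_orig <- igraph::as_edgelist(g2)
  el_back <- igraph::as_edgelist(back)
  key <- function(el) sort(paste(el[, 1], el[, 2]))
  expect_equal(key(el_back), key(el_orig))
  expect_equal(sort(igraph::E(back)$weight), sort(igraph::E(g2)$weight))
})

test_that("target-count tables summarize per-TF regulon sizes", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("tf\tspecies\tgene",
               "Rap1\tSc\tg1", "Rap1\tSc\tg2", "Rap1\tSc\tg2",
               "Tbf1\tCa\tg9"), f)
  tc <- read_target_counts(f)
  expect_equal(tc$n_targets[tc$tf == "Rap1"], 2)  # duplicates collapse
  expect_equal(tc$n_targets[tc$tf == "Tbf1"], 1)
})
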
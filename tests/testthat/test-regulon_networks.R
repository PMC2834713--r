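# Enrichment statistics, regulon overlap, GO enrichment, nulls, networks.

test_that("hypergeometric tail matches closed forms and enumeration", {
  expect_equal(hypergeometric_tail(5, 5, 5, 10), 1 / choose(10, 5))
  expect_equal(hypergeometric_tail(0, 3, 4, 10), 1)
  expect_equal(hypergeometric_tail(2, 3, 3, 6), 0.5)  # (9 + 1) / 20 draws
  expect_error(hypergeometric_tail(4, 3, 3, 6), "min")
  expect_error(hypergeometric_tail(1, 7, 3, 6), "N")
  # spot-check against literal enumeration at a handful of sizes
  for (case in list(c(2, 4, 3, 9), c(1, 2, 5, 8), c(3, 5, 4, 11))) {
    expect_equal(hypergeometric_tail(case[1], case[2], case[3], case[4]),
                 hyper_tail_enum(case[1], case[2], case[3], case[4]),
                 tolerance = 1e-12)
  }
})

test_that("regulon overlap counts ortholog pairs and labels significance", {
  pairs <- data.frame(gene1 = sprintf("a%03d", 1:100),
                      gene2 = sprintf("b%03d", 1:100))
  om <- orthology_map(pairs)
  # identical regulons of size 10 in a universe of 100 pairs
  a <- sprintf("a%03d", 1:10); b <- sprintf("b%03d", 1:10)
  ov <- regulon_overlap(a, b, om)
  expect_equal(ov$k, 10)
  expect_equal(ov$p, hypergeometric_tail(10, 10, 10, 100))
  expect_true(ov$significant)
  # disjoint regulons: k = 0, p = 1
  ov0 <- regulon_overlap(sprintf("a%03d", 1:10), sprintf("b%03d", 11:20), om)
  expect_equal(ov0$k, 0)
  expect_equal(ov0$p, 1)
  expect_false(ov0$significant)
  # many-to-many orthology counts at the pair level
  om2 <- orthology_map(data.frame(gene1 = c("a1", "a1", "a2"),
                                  gene2 = c("b1", "b2", "b3")))
  ov2 <- regulon_overlap("a1", c("b1", "b2"), om2)
  expect_equal(ov2$N, 3)
  expect_equal(ov2$k, 2)
})

test_that("overlap p-values agree with a permutation oracle", {
  set.seed(31)
  pairs <- data.frame(gene1 = sprintf("a%03d", 1:200),
                      gene2 = sprintf("b%03d", 1:200))
  om <- orthology_map(pairs)
  n_perm <- 4000
  for (rep in 1:8) {
    a <- sample(pairs$gene1, 20)
    b <- sample(pairs$gene2, 20)
    ov <- regulon_overlap(a, b, om)
    b_idx <- match(b, pairs$gene2)
    a_idx <- match(a, pairs$gene1)
    perm_k <- replicate(n_perm, length(intersect(sample(200, 20), b_idx)))
    p_perm <- mean(perm_k >= ov$k)
    se <- sqrt(max(p_perm, 1 / n_perm) * (1 - min(p_perm, 1 - 1e-9)) / n_perm)
    expect_lt(abs(ov$p - p_perm), 3 * se + 1e-9)
  }
})

test_that("genome coverage is a percentage of the universe", {
  expect_equal(genome_coverage(sprintf("g%03d", 1:595),
                               sprintf("g%03d", 1:5950)), 10)
  expect_equal(genome_coverage(character(0), letters), 0)
  # coverage ratio between species mirrors fold-change reporting
  cov1 <- genome_coverage(paste0("g", 1:60), paste0("g", 1:600))
  cov2 <- genome_coverage(paste0("g", 1:6), paste0("g", 1:600))
  expect_equal(cov1 / cov2, 10)
  expect_error(genome_coverage("g1", character(0)), "empty")
})

test_that("GO enrichment computes per-term tails on expanded annotations", {
  universe <- sprintf("g%02d", 1:20)
  go <- expand_go_annotations(
    list(term5 = sprintf("g%02d", 1:5), other = sprintf("g%02d", 10:12)),
    data.frame(child = c("term5", "other"), parent = c("root", "root")))
  targets <- c(sprintf("g%02d", 1:4), "g20")  # 4 of the 5 term genes
  res <- go_enrichment(targets, go, universe)
  expect_equal(res$p[res$term == "term5"], 76 / 15504, tolerance = 1e-12)
  expect_true(res$display[res$term == "term5"])
  # child enrichment propagates: root contains >= the child's overlap
  expect_gte(res$k[res$term == "root"], res$k[res$term == "term5"])
  # degenerate: target set = universe gives p = 1 everywhere
  res_all <- go_enrichment(universe, go, universe)
  expect_true(all(res_all$p == 1))
  expect_error(go_enrichment("not_in_universe", go, universe), "subset")
  expect_error(
    go_enrichment(targets, go_annotation_set(list(t = "g01")), universe),
    "expanded")
})

test_that("randomized nulls honor length weighting and seeding", {
  promoters <- data.frame(region_id = sprintf("r%02d", 1:10),
                          length = c(100, rep(1, 9)))
  stat_long <- function(ids) as.numeric("r01" %in% ids)
  null_w <- randomized_target_null(1, promoters, stat_long,
                                   weight_by_length = TRUE,
                                   n_draws = 20000, seed = 4)
  # closed form: P(long) = 100 / (100 + P - 1)
  expect_equal(mean(null_w), 100 / 109, tolerance = 0.02)
  null_u <- randomized_target_null(1, promoters, stat_long,
                                   weight_by_length = FALSE,
                                   n_draws = 20000, seed = 4)
  expect_equal(mean(null_u), 1 / 10, tolerance = 0.02)
  # equal lengths: weighting is a no-op distributionally
  eq <- data.frame(region_id = sprintf("r%02d", 1:10), length = rep(7, 10))
  s <- function(ids) mean(ids %in% sprintf("r%02d", 1:5))
  d1 <- randomized_target_null(4, eq, s, TRUE, n_draws = 5000, seed = 9)
  d2 <- randomized_target_null(4, eq, s, FALSE, n_draws = 5000, seed = 10)
  expect_equal(mean(d1), mean(d2), tolerance = 0.02)
  # seeded determinism
  expect_identical(
    randomized_target_null(3, eq, s, n_draws = 200, seed = 11),
    randomized_target_null(3, eq, s, n_draws = 200, seed = 11))
  expect_warning(randomized_target_null(1, eq, s, n_draws = 10, seed = 1),
                 "coarse")
})

test_that("network construction covers the three modes", {
  mk_reg <- function(tf, targets) {
    structure(list(tf_id = tf, species_id = "sp", targets = targets,
                   peaks = data.frame()), class = "regulon")
  }
  regs <- list(A = mk_reg("A", c("gB", "gx", "gA")), B = mk_reg("B", "gy"))
  node_genes <- data.frame(node_id = c("A", "B"), gene_id = c("gA", "gB"))
  g <- build_network(regs, "tf_tf", node_genes = node_genes)
  el <- igraph::as_edgelist(g)
  # A binds B's gene and its own promoter (self-loop); B binds neither
  expect_setequal(paste(el[, 1], el[, 2]), c("A B", "A A"))
  expect_equal(unname(igraph::degree(g, "B", mode = "out")), 0)
  # regulon with no TF genes: isolated node, 0 out-edges
  regs2 <- list(A = mk_reg("A", "gz"), B = mk_reg("B", character(0)))
  g2 <- build_network(regs2, "tf_tf", node_genes = node_genes)
  expect_equal(igraph::ecount(g2), 0)
  # tf_go mode wires TFs to displayed terms
  go_res <- list(A = data.frame(term = c("t1", "t2"), p = c(1e-3, 0.5),
                                display = c(TRUE, FALSE)))
  g3 <- build_network(regs["A"], "tf_go", go_results = go_res)
  el3 <- igraph::as_edgelist(g3)
  expect_equal(paste(el3[, 1], el3[, 2]), "A t1")
  expect_equal(igraph::V(g3)$type, c("TF", "GO"))
  expect_error(build_network(regs, "tf_tf"), "node_genes")
})

test_that("conserved-edge counting identifies edges through orthology", {
  mk_net <- function(edges) {
    vs <- unique(as.vector(edges))
    g <- igraph::make_empty_graph(directed = TRUE)
    g <- igraph::add_vertices(g, length(vs), name = vs)
    igraph::add_edges(g, match(as.vector(t(edges)), vs))
  }
  om <- orthology_map(data.frame(gene1 = c("a1", "a2", "a3"),
                                 gene2 = c("b1", "b2", "b3")))
  # identical networks under 1:1 orthology: all edges conserved
  na <- mk_net(rbind(c("a1", "a2"), c("a2", "a3")))
  nb <- mk_net(rbind(c("b1", "b2"), c("b2", "b3")))
  ce <- conserved_edges(na, nb, om)
  expect_equal(ce$n_conserved, 2)
  expect_equal(ce$n_total, 2)
  # disjoint edge sets: nothing conserved, union counts all
  nb2 <- mk_net(rbind(c("b3", "b1")))
  ce2 <- conserved_edges(na, nb2, om)
  expect_equal(ce2$n_conserved, 0)
  expect_equal(ce2$n_total, 3)
  # 1 shared of 3 union edges
  nb3 <- mk_net(rbind(c("b1", "b2"), c("b3", "b2")))
  ce3 <- conserved_edges(na, nb3, om)
  expect_equal(ce3$n_conserved, 1)
  expect_equal(ce3$n_total, 3)
})
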
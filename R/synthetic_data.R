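# Seeded synthetic two-species datasets with planted ground truth:
# genomes, gene layouts, orthology, GO annotations, planted binding sites
# carrying a motif, and simulated probe tracks. Everything is a pure
# function of (spec, seed), so every pipeline stage is testable without
# external data.

#' Specification of one synthetic species
#'
#' Defaults give a compact genome (2 chromosomes x ~250 genes, ~1 Mb
#' total) with tiling-array probe densities in the range of real
#' full-genome designs (17-20 probes/kb).
#'
#' @param species_id label used in gene ids and tracks.
#' @param n_chromosomes number of chromosomes.
#' @param genes_per_chromosome genes per chromosome.
#' @param gene_length_mean,gene_length_sd gene span distribution (bp;
#'   truncated at 300).
#' @param intergenic_length_mean,intergenic_length_sd intergenic gap
#'   distribution (bp; truncated at 200).
#' @param probe_density probes per kb.
#' @param frac_rp,frac_tf,frac_kinase fractions of genes flagged RP / TF /
#'   kinase.
#' @return an object of class `species_spec`.
#' @export
species_spec <- function(species_id, n_chromosomes = 2,
                         genes_per_chromosome = 250,
                         gene_length_mean = 1000, gene_length_sd = 200,
                         intergenic_length_mean = 1000,
                         intergenic_length_sd = 300,
                         probe_density = 20,
                         frac_rp = 0.05, frac_tf = 0.04,
                         frac_kinase = 0.03) {
  stopifnot(probe_density > 0, gene_length_mean > 0,
            intergenic_length_mean > 0)
  structure(as.list(environment()), class = "species_spec")
}

#' Noise model for simulated ChIP experiments
#'
#' @param probe_sd i.i.d. Gaussian probe noise sd (log2 units).
#' @param peak_width_bp sd of the Gaussian enrichment peak shape (bp).
#' @param baseline baseline log2 level.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(probe_sd = 0.5, peak_width_bp = 100, baseline = 0) {
  stopifnot(probe_sd >= 0, peak_width_bp > 0)
  structure(list(probe_sd = probe_sd, peak_width_bp = peak_width_bp,
                 baseline = baseline), class = "noise_model")
}

layout_one_species <- function(spec) {
  genes <- list(); sizes <- numeric(0); genome <- character(0)
  grids <- list()
  gidx <- 0
  for (ci in seq_len(spec$n_chromosomes)) {
    chr <- sprintf("%s_chr%d", spec$species_id, ci)
    n <- spec$genes_per_chromosome
    ig <- pmax(200, round(rnorm(n + 1, spec$intergenic_length_mean,
                                spec$intergenic_length_sd)))
    gl <- pmax(300, round(rnorm(n, spec$gene_length_mean,
                                spec$gene_length_sd)))
    pos <- 0
    st <- en <- integer(n)
    for (i in seq_len(n)) {
      pos <- pos + ig[i]
      st[i] <- pos
      pos <- pos + gl[i]
      en[i] <- pos
    }
    size <- pos + ig[n + 1]
    sizes[chr] <- size
    genes[[chr]] <- data.frame(
      gene_id = sprintf("%s_g%04d", spec$species_id, gidx + seq_len(n)),
      chrom = chr, start = st, end = en,
      strand = sample(c("+", "-"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    gidx <- gidx + n
    genome[chr] <- paste(sample(DNA_BASES, size, replace = TRUE),
                         collapse = "")
    spacing <- 1000 / spec$probe_density
    base <- seq(spacing, size - spacing, by = spacing)
    gp <- sort(unique(round(base + runif(length(base), -0.2, 0.2) * spacing)))
    grids[[chr]] <- gp[gp >= 0 & gp < size]
  }
  genes <- do.call(rbind, genes)
  rownames(genes) <- NULL
  ngen <- nrow(genes)
  genes$is_rp <- seq_len(ngen) %in% sample(ngen, round(spec$frac_rp * ngen))
  genes$is_tf <- seq_len(ngen) %in% sample(ngen, round(spec$frac_tf * ngen))
  genes$is_kinase <- seq_len(ngen) %in%
    sample(ngen, round(spec$frac_kinase * ngen))
  list(spec = spec, genes = genes, chrom_sizes = sizes, genome = genome,
       probe_grid = grids)
}

#' Simulate a pair of species with orthology, GO and ground-truth skeleton
#'
#' Lays out genes and intergenic gaps on i.i.d.-uniform ACGT chromosomes,
#' builds a 1:1 orthology over `ortholog_fraction` of the smaller gene
#' set, and generates GO annotations under a two-level hierarchy (leaf
#' terms under four branch terms under one root). One leaf term is the
#' "ribosome" term, annotated exactly to the RP-flagged genes (mirrored
#' through orthology in species B), so planted RP regulons are
#' GO-enrichable. Fully seeded: identical outputs for identical seeds.
#'
#' @param spec_a,spec_b [species_spec()]s; defaults model a 20 and a 17
#'   probes/kb array design.
#' @param ortholog_fraction fraction of genes with a 1:1 ortholog.
#' @param n_go_terms number of leaf GO terms.
#' @param seed RNG seed.
#' @return an object of class `regrewire_sim`: list with `species` (per
#'   species: `spec`, `genes`, `chrom_sizes`, `genome`, `regions`,
#'   `probe_grid`), `orthology`, `go` (per species
#'   [go_annotation_set()]), and an empty `truth` skeleton.
#' @export
simulate_species_pair <- function(spec_a = species_spec("SpA",
                                                        probe_density = 20),
                                  spec_b = species_spec("SpB",
                                                        probe_density = 17),
                                  ortholog_fraction = 0.8,
                                  n_go_terms = 16, seed = 1) {
  stopifnot(ortholog_fraction >= 0, ortholog_fraction <= 1)
  withr::with_seed(seed, {
    A <- layout_one_species(spec_a)
    B <- layout_one_species(spec_b)
    # 1:1 orthology over a random subset of each species' genes
    k <- round(ortholog_fraction * min(nrow(A$genes), nrow(B$genes)))
    ga <- sample(A$genes$gene_id, k)
    gb <- sample(B$genes$gene_id, k)
    orth <- orthology_map(data.frame(gene1 = ga, gene2 = gb))
    # RP flags in B follow orthology where possible
    a_rp <- A$genes$gene_id[A$genes$is_rp]
    b_rp_orth <- orth$pairs$gene2[orth$pairs$gene1 %in% a_rp]
    B$genes$is_rp <- B$genes$gene_id %in% b_rp_orth
    need <- round(spec_b$frac_rp * nrow(B$genes)) - sum(B$genes$is_rp)
    if (need > 0) {
      extra <- sample(which(!B$genes$is_rp), need)
      B$genes$is_rp[extra] <- TRUE
    }
    # GO: two-level hierarchy shared between species
    leaves <- sprintf("GO:L%02d", seq_len(n_go_terms))
    branches <- sprintf("GO:B%d", 1:4)
    hier <- rbind(
      data.frame(child = leaves,
                 parent = branches[(seq_len(n_go_terms) - 1) %% 4 + 1]),
      data.frame(child = branches, parent = "GO:ROOT"))
    terms_a <- list()
    terms_a[["GO:L01"]] <- a_rp  # the ribosome term
    for (tm in leaves[-1]) {
      terms_a[[tm]] <- sample(A$genes$gene_id,
                              min(nrow(A$genes), sample(15:40, 1)))
    }
    # species B annotations: translate species A memberships for
    # orthologous genes, plus random members among unmapped genes
    a2b <- split(orth$pairs$gene2, orth$pairs$gene1)
    unmapped_b <- setdiff(B$genes$gene_id, orth$universe2)
    terms_b <- lapply(terms_a, function(g) {
      tr <- unique(unlist(a2b[intersect(g, names(a2b))], use.names = FALSE))
      extra <- if (length(unmapped_b) > 0) {
        sample(unmapped_b, min(length(unmapped_b), 5))
      } else character(0)
      union(tr, extra)
    })
    terms_b[["GO:L01"]] <- B$genes$gene_id[B$genes$is_rp]
    A$regions <- compute_intergenic_regions(A$genes, A$chrom_sizes)
    B$regions <- compute_intergenic_regions(B$genes, B$chrom_sizes)
    sim <- structure(list(
      species = setNames(list(A, B),
                         c(spec_a$species_id, spec_b$species_id)),
      orthology = orth,
      go = setNames(list(go_annotation_set(terms_a, hier),
                         go_annotation_set(terms_b, hier)),
                    c(spec_a$species_id, spec_b$species_id)),
      truth = list(
        sites = data.frame(tf_id = character(0), species_id = character(0),
                           region_id = character(0), chrom = character(0),
                           position = integer(0), amplitude = numeric(0),
                           strand = character(0)),
        motifs = list(), regulons = list(),
        conserved_pairs = data.frame(gene1 = character(0),
                                     gene2 = character(0)))),
      class = "regrewire_sim")
    sim
  })
}

#' @export
print.regrewire_sim <- function(x, ...) {
  cat(sprintf(
    "regrewire_sim: species %s; %d ortholog pairs; %d planted site(s)\n",
    paste(names(x$species), collapse = " / "),
    nrow(x$orthology$pairs), nrow(x$truth$sites)))
  invisible(x)
}

#' Sample candidate target promoter regions
#'
#' Picks intergenic regions with a non-empty promoter gene set, optionally
#' restricted to promoters of orthologous genes and/or of genes in a given
#' set (e.g. one GO term).
#'
#' @param sim a `regrewire_sim`.
#' @param species species id.
#' @param n number of regions to sample.
#' @param ortholog_only require every promoter gene to have an ortholog.
#' @param gene_set optionally require at least one promoter gene in this
#'   set.
#' @param seed RNG seed.
#' @return character vector of region ids.
#' @export
sample_target_regions <- function(sim, species, n, ortholog_only = FALSE,
                                  gene_set = NULL, seed = 1) {
  sp <- sim$species[[species]]
  uni <- if (species == names(sim$species)[1]) sim$orthology$universe1 else
    sim$orthology$universe2
  ok <- vapply(seq_len(nrow(sp$regions)), function(i) {
    p <- sp$regions$promoter_of[[i]]
    if (length(p) == 0) return(FALSE)
    if (ortholog_only && !all(p %in% uni)) return(FALSE)
    if (!is.null(gene_set) && !any(p %in% gene_set)) return(FALSE)
    TRUE
  }, logical(1))
  cand <- sp$regions$region_id[ok]
  if (length(cand) < n) stop("only ", length(cand), " candidate regions")
  withr::with_seed(seed, sample(cand, n))
}

plant_one_site <- function(sim, species, tf_id, rid, motif, amplitude) {
  sp <- sim$species[[species]]
  r <- sp$regions[sp$regions$region_id == rid, , drop = FALSE]
  len <- 6L + motif$gap
  if (r$end - r$start < len + 2) {
    message("region ", rid, " shorter than motif; skipped")
    return(sim)
  }
  start <- r$start + sample.int(r$end - r$start - len + 1, 1) - 1L
  instance <- paste0(motif$triplet1,
                     paste(sample(DNA_BASES, motif$gap, replace = TRUE),
                           collapse = ""),
                     motif$triplet2)
  strand <- sample(c("+", "-"), 1)
  if (strand == "-") instance <- revcomp_chr(instance)
  g <- sim$species[[species]]$genome[[r$chrom]]
  substr(g, start + 1, start + len) <- instance
  sim$species[[species]]$genome[[r$chrom]] <- g
  site <- data.frame(tf_id = tf_id, species_id = species, region_id = rid,
                     chrom = r$chrom,
                     position = as.integer(start + len %/% 2),
                     amplitude = amplitude, strand = strand,
                     stringsAsFactors = FALSE)
  sim$truth$sites <- rbind(sim$truth$sites, site)
  key <- paste(species, tf_id, sep = ".")
  sim$truth$regulons[[key]] <- sort(union(sim$truth$regulons[[key]],
                                          r$promoter_of[[1]]))
  sim
}

#' Plant binding sites carrying a motif into a simulated genome
#'
#' Writes one motif instance (random gap bases, random strand) at a
#' seeded uniform position inside each chosen intergenic region of the
#' first species, records the sites, the motif and the implied true
#' regulon, and mirrors a `conservation` fraction of the sites into the
#' partner species at the promoters of the orthologous genes.
#'
#' @param sim a `regrewire_sim`.
#' @param species species to plant in (default: first).
#' @param tf_id factor label.
#' @param target_regions region ids (see [sample_target_regions()]).
#' @param motif a [minimotif()].
#' @param amplitude peak height (log2 units) recorded for the sites.
#' @param conservation fraction of sites mirrored into the partner
#'   species via orthology (default 0).
#' @param seed RNG seed.
#' @return the updated `regrewire_sim`.
#' @export
plant_binding_sites <- function(sim, species = names(sim$species)[1],
                                tf_id, target_regions, motif,
                                amplitude = 4, conservation = 0, seed = 1) {
  stopifnot(inherits(motif, "minimotif"))
  other <- setdiff(names(sim$species), species)[1]
  withr::with_seed(seed, {
    for (rid in target_regions) {
      sim <- plant_one_site(sim, species, tf_id, rid, motif, amplitude)
    }
    sim$truth$motifs[[paste(species, tf_id, sep = ".")]] <- motif
    n_cons <- round(conservation * length(target_regions))
    if (n_cons > 0 && !is.na(other)) {
      sp <- sim$species[[species]]
      osp <- sim$species[[other]]
      fwd <- if (species == names(sim$species)[1]) {
        split(sim$orthology$pairs$gene2, sim$orthology$pairs$gene1)
      } else {
        split(sim$orthology$pairs$gene1, sim$orthology$pairs$gene2)
      }
      gene2region <- list()
      for (i in seq_len(nrow(osp$regions))) {
        for (g in osp$regions$promoter_of[[i]]) {
          if (is.null(gene2region[[g]])) {
            gene2region[[g]] <- osp$regions$region_id[i]
          }
        }
      }
      mirrored <- 0
      planted_b <- character(0)
      for (rid in target_regions) {
        if (mirrored >= n_cons) break
        r <- sp$regions[sp$regions$region_id == rid, , drop = FALSE]
        for (g in r$promoter_of[[1]]) {
          og <- fwd[[g]]
          if (is.null(og)) next
          orid <- gene2region[[og[1]]]
          if (is.null(orid) || orid %in% planted_b) next
          sim <- plant_one_site(sim, other, tf_id, orid, motif, amplitude)
          sim$truth$conserved_pairs <-
            rbind(sim$truth$conserved_pairs,
                  data.frame(gene1 = g, gene2 = og[1],
                             stringsAsFactors = FALSE))
          planted_b <- c(planted_b, orid)
          mirrored <- mirrored + 1
          break
        }
      }
      if (mirrored < n_cons) {
        message("could only mirror ", mirrored, " of ", n_cons,
                " conserved sites")
      }
      sim$truth$motifs[[paste(other, tf_id, sep = ".")]] <- motif
    }
    sim
  })
}

#' Simulate one ChIP-chip experiment from planted truth
#'
#' Probe positions come from the species' jittered array grid; the signal
#' at probe `p` is `baseline + sum_sites amplitude *
#' exp(-(p - site)^2 / (2 w^2)) + Normal(0, probe_sd)`.
#'
#' @param sim a `regrewire_sim` with planted sites.
#' @param species species id.
#' @param tf_id factor whose sites drive the signal.
#' @param noise a [noise_model()].
#' @param seed RNG seed.
#' @return a [probe_track()].
#' @export
simulate_chip_experiment <- function(sim, species, tf_id,
                                     noise = noise_model(), seed = 1) {
  sp <- sim$species[[species]]
  sites <- sim$truth$sites
  sites <- sites[sites$species_id == species & sites$tf_id == tf_id, ,
                 drop = FALSE]
  w <- noise$peak_width_bp
  withr::with_seed(seed, {
    tracks <- lapply(names(sp$probe_grid), function(chr) {
      p <- sp$probe_grid[[chr]]
      mu <- rep(noise$baseline, length(p))
      s <- sites[sites$chrom == chr, , drop = FALSE]
      for (i in seq_len(nrow(s))) {
        mu <- mu + s$amplitude[i] * exp(-(p - s$position[i])^2 / (2 * w^2))
      }
      data.frame(chrom = chr, pos = p,
                 value = mu + rnorm(length(p), 0, noise$probe_sd),
                 stringsAsFactors = FALSE)
    })
    probe_track(do.call(rbind, tracks), experiment_id = tf_id,
                species_id = species)
  })
}

#' Precision/recall of called peaks against planted sites
#'
#' Greedy one-to-one matching by genomic distance: candidate
#' (called, planted) pairs within `tolerance_bp` on the same chromosome
#' are matched closest-first. Also reports gene-level precision/recall
#' when a regulon and the truth regulon are available.
#'
#' @param called a peaks data.frame (`chrom`, `pos`) or a `regulon`.
#' @param sim a `regrewire_sim` (its `truth` is used), or a truth `sites`
#'   data.frame.
#' @param species,tf_id which planted sites to evaluate against.
#' @param tolerance_bp maximum matching distance (default 50).
#' @return list with `n_called`, `n_true`, `n_matched`, `precision`
#'   (NA when nothing was called), `recall`, `mean_abs_error`,
#'   `gene_precision`, `gene_recall` (NA unless gene sets available).
#' @export
evaluate_recovery <- function(called, sim, species = NULL, tf_id = NULL,
                              tolerance_bp = 50) {
  truth_sites <- if (inherits(sim, "regrewire_sim")) sim$truth$sites else sim
  if (!is.null(species)) {
    truth_sites <- truth_sites[truth_sites$species_id == species, ,
                               drop = FALSE]
  }
  if (!is.null(tf_id)) {
    truth_sites <- truth_sites[truth_sites$tf_id == tf_id, , drop = FALSE]
  }
  peaks <- if (inherits(called, "regulon")) called$peaks else called
  nc <- nrow(peaks); nt <- nrow(truth_sites)
  cand <- list()
  for (i in seq_len(nc)) {
    same <- which(truth_sites$chrom == peaks$chrom[i])
    d <- abs(truth_sites$position[same] - peaks$pos[i])
    ok <- d <= tolerance_bp
    if (any(ok)) {
      cand[[length(cand) + 1]] <- data.frame(called = i, true = same[ok],
                                             d = d[ok])
    }
  }
  cand <- do.call(rbind, cand)
  matched <- 0; errs <- numeric(0)
  if (!is.null(cand) && nrow(cand) > 0) {
    cand <- cand[order(cand$d), , drop = FALSE]
    used_c <- used_t <- integer(0)
    for (i in seq_len(nrow(cand))) {
      if (cand$called[i] %in% used_c || cand$true[i] %in% used_t) next
      used_c <- c(used_c, cand$called[i])
      used_t <- c(used_t, cand$true[i])
      errs <- c(errs, cand$d[i])
      matched <- matched + 1
    }
  }
  gene_p <- gene_r <- NA_real_
  if (inherits(called, "regulon") && inherits(sim, "regrewire_sim") &&
      !is.null(species) && !is.null(tf_id)) {
    true_genes <- sim$truth$regulons[[paste(species, tf_id, sep = ".")]]
    if (!is.null(true_genes)) {
      if (length(called$targets) > 0) {
        gene_p <- length(intersect(called$targets, true_genes)) /
          length(called$targets)
      }
      gene_r <- length(intersect(called$targets, true_genes)) /
        length(true_genes)
    }
  }
  list(n_called = nc, n_true = nt, n_matched = matched,
       precision = if (nc > 0) matched / nc else NA_real_,
       recall = if (nt > 0) matched / nt else NA_real_,
       mean_abs_error = if (matched > 0) mean(errs) else NA_real_,
       gene_precision = gene_p, gene_recall = gene_r)
}

#' Write a simulated dataset to standard file formats
#'
#' FASTA genomes, GFF3 annotations, chromosome-size / orthology / GO /
#' gene-list TSVs and a planted-truth TSV, i.e. the same formats the
#' pipeline reads back.
#'
#' @param sim a `regrewire_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (spn in names(sim$species)) {
    sp <- sim$species[[spn]]
    fa <- Biostrings::DNAStringSet(unlist(sp$genome))
    Biostrings::writeXStringSet(fa, file.path(dir, paste0(spn, ".fasta")))
    write_gene_annotations(sp$genes, file.path(dir, paste0(spn, ".gff3")))
    write.table(data.frame(chrom = names(sp$chrom_sizes),
                           size = as.integer(sp$chrom_sizes)),
                file.path(dir, paste0(spn, ".chrom_sizes.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    go <- sim$go[[spn]]
    ann <- data.frame(
      term = rep(names(go$terms), lengths(go$terms)),
      gene = unlist(go$terms, use.names = FALSE))
    write.table(ann, file.path(dir, paste0(spn, ".go.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write.table(sim$orthology$pairs, file.path(dir, "orthology.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  write.table(sim$go[[1]]$hierarchy, file.path(dir, "go_hierarchy.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  write.table(sim$truth$sites, file.path(dir, "truth_sites.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
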
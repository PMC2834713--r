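# Peak calling: blur kernel, spline interpolation, greedy masked
# extraction, Z-calling, target assignment, differential ORF signal.

test_that("gaussian blur matches the normalized kernel and its identities", {
  tr <- probe_track(data.frame(chrom = "c", pos = c(0, 100, 200),
                               value = c(0, 1, 0)))
  # sigma 0 is the identity
  expect_equal(gaussian_blur(tr, 0)$probes$value, c(0, 1, 0))
  # constant track stays constant under any sigma (weights normalize)
  trc <- probe_track(data.frame(chrom = "c", pos = c(0, 50, 130, 400),
                                value = rep(2.5, 4)))
  expect_equal(gaussian_blur(trc, 80)$probes$value, rep(2.5, 4))
  # hand-evaluated kernel: center probe at sigma = gap = 100
  b <- gaussian_blur(tr, 100)$probes$value
  w <- exp(-0.5)
  expect_equal(b[2], 1 / (1 + 2 * w), tolerance = 1e-9)
  expect_equal(b[1], w / (1 + w + exp(-2)), tolerance = 1e-9)
  # raw stats carried over unchanged for downstream Z-calling
  expect_equal(gaussian_blur(tr, 100)$mean_raw, tr$mean_raw)
})

test_that("natural spline interpolation is exact at probes and linear limits", {
  # collinear probes reproduce the line at every bp
  tr <- probe_track(data.frame(chrom = "c", pos = c(0, 40, 100, 160),
                               value = c(0, 40, 100, 160) * 0.02 + 1))
  s <- interpolate_to_bp(tr)
  expect_equal(s$values, (0:160) * 0.02 + 1, tolerance = 1e-9)
  # two probes: linear interpolation (natural boundary conditions)
  tr2 <- probe_track(data.frame(chrom = "c", pos = c(10, 20),
                                value = c(0, 5)))
  s2 <- interpolate_to_bp(tr2)
  expect_equal(s2$values, seq(0, 5, by = 0.5), tolerance = 1e-9)
  # probe positions recover probe values to machine precision
  set.seed(5)
  p <- sort(sample(0:500, 12))
  v <- rnorm(12)
  tr3 <- probe_track(data.frame(chrom = "c", pos = p, value = v))
  s3 <- interpolate_to_bp(tr3)
  expect_equal(s3$values[p - s3$start + 1], v, tolerance = 1e-12)
  expect_error(interpolate_to_bp(
    probe_track(data.frame(chrom = "c", pos = 1, value = 1))), ">= 2")
})

test_that("greedy extraction obeys the masking window and ordering", {
  spikes <- function(centers, heights, n = 2000) {
    v <- numeric(n)
    v[centers + 1] <- heights  # 0-based centers
    v
  }
  # single summit: argmax found
  s <- as_signal_track(spikes(500, 4))
  expect_equal(extract_peaks(s, floor = 0.5)$pos, 500)
  # two summits 300 bp apart: second falls inside the +/-300 mask
  s2 <- as_signal_track(spikes(c(500, 800), c(4, 3.5)))
  p2 <- extract_peaks(s2, floor = 0.5)
  expect_equal(p2$pos, 500)
  # 700 bp apart: both emitted, tallest first
  s3 <- as_signal_track(spikes(c(500, 1200), c(4, 3.5)))
  p3 <- extract_peaks(s3, floor = 0.5)
  expect_equal(p3$pos, c(500, 1200))
  expect_equal(p3$height, c(4, 3.5))
  # no two peaks within the mask window; heights non-increasing
  set.seed(7)
  s4 <- as_signal_track(rnorm(5000))
  p4 <- extract_peaks(s4)
  expect_true(all(diff(sort(p4$pos)) > 300))
  expect_true(all(diff(p4$height) <= 1e-12))
})

test_that("extraction agrees with the brute-force mask-array oracle", {
  set.seed(13)
  for (rep in 1:10) {
    v <- rnorm(sample(500:3000, 1)) + sin(seq(0, 20, length.out = 1000))[1]
    s <- as_signal_track(v)
    fast <- extract_peaks(s, floor = 0)
    slow <- brute_extract_peaks(v, floor = 0)
    expect_equal(fast$pos, slow$pos)
    expect_equal(fast$height, slow$height)
  }
})

test_that("peak positions shift-invariant, Z-calling equivariant", {
  set.seed(17)
  v <- rnorm(3000, sd = 0.3) +
    3 * exp(-((1:3000) - 700)^2 / 800) + 2 * exp(-((1:3000) - 2200)^2 / 800)
  p0 <- extract_peaks(as_signal_track(v), floor = -Inf, max_peaks = 5)
  p1 <- extract_peaks(as_signal_track(v + 10), floor = -Inf, max_peaks = 5)
  expect_equal(p0$pos, p1$pos)
  # calling: threshold shifts with the mean
  sig0 <- call_significant_peaks(p0, c(mean_raw = 0, sd_raw = 0.5), z = 2)
  sig1 <- call_significant_peaks(p1, c(mean_raw = 10, sd_raw = 0.5), z = 2)
  expect_equal(sig0$pos, sig1$pos)
  expect_equal(sig0$zscore, sig1$zscore)
})

test_that("Z-score calling applies mean + z * sd on raw stats", {
  pk <- data.frame(chrom = "c", pos = c(1, 2, 3), height = c(2.5, 1.5, 0.1),
                   rank = 1:3)
  sig <- call_significant_peaks(pk, c(mean_raw = 0, sd_raw = 1), z = 2)
  expect_equal(sig$height, 2.5)
  expect_equal(sig$zscore, 2.5)
  all_kept <- call_significant_peaks(pk, c(mean_raw = 0, sd_raw = 1), z = 0)
  expect_equal(nrow(all_kept), 3)  # z = 0 keeps everything above the mean
  expect_error(call_significant_peaks(pk, c(mean_raw = 0, sd_raw = 0)),
               "degenerate")
})

test_that("targets come from promoter regions; intragenic peaks excluded", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "c",
                      start = c(2000, 6000), end = c(3000, 7000),
                      strand = c("-", "+"), stringsAsFactors = FALSE)
  regions <- compute_intergenic_regions(genes, c(c = 10000))
  pk <- data.frame(chrom = "c", pos = c(4500, 2500, 4600),
                   height = c(3, 2.8, 2.6), rank = 1:3, zscore = c(3, 2.8, 2.6))
  reg <- assign_targets(pk, regions, genes, tf_id = "TF")
  # divergent middle region targets both flanking genes
  expect_setequal(reg$targets, c("g1", "g2"))
  # the intragenic peak is flagged and contributes nothing
  expect_true(reg$peaks$intragenic[reg$peaks$pos == 2500])
  # two peaks in one promoter count the gene once
  expect_equal(sum(reg$targets == "g2"), 1)
})

test_that("differential ORF signal flags planted decreases and RP fraction", {
  set.seed(23)
  n_genes <- 50; probes_per <- 10
  genes <- data.frame(gene_id = sprintf("g%02d", 1:n_genes), chrom = "c",
                      start = (0:(n_genes - 1)) * 1000,
                      end = (0:(n_genes - 1)) * 1000 + 900,
                      strand = "+", stringsAsFactors = FALSE)
  pos <- as.vector(sapply(genes$start, function(s) s + seq(50, 850, length.out = probes_per)))
  a <- rnorm(length(pos), 0, 0.1)
  b <- rnorm(length(pos), 0, 0.1)
  planted <- 1:10   # decreased ORFs; 8 of them RP
  genes$is_rp <- genes$gene_id %in% sprintf("g%02d", c(1:8, 30, 40))
  for (g in planted) {
    sel <- pos >= genes$start[g] & pos < genes$end[g]
    a[sel] <- a[sel] - 3
  }
  ta <- probe_track(data.frame(chrom = "c", pos = pos, value = a))
  tb <- probe_track(data.frame(chrom = "c", pos = pos, value = b))
  res <- differential_orf_signal(ta, tb, genes)
  expect_setequal(res$gene_id[res$significant], sprintf("g%02d", planted))
  expect_equal(attr(res, "rp_fraction"), 0.8)
  # identical tracks: all zero, nothing significant
  res0 <- differential_orf_signal(ta, ta, genes)
  expect_true(all(res0$mean_diff == 0))
  expect_false(any(res0$significant))
  expect_error(differential_orf_signal(
    ta, probe_track(data.frame(chrom = "c", pos = pos + 1, value = b)),
    genes), "grid")
})
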
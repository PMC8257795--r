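test_that("marker filters apply the quoted strict thresholds", {
  # 20 samples; craft per-site properties
  n <- 20
  calls <- cbind(
    c(rep(1L, 1), rep(2L, 19)),          # MAF = 0.025 < 0.05 -> drop
    c(rep(1L, 17), rep(2L, 3)),          # het freq 0.85 > 0.8 -> drop
    c(rep(1L, 10), rep(2L, 7), NA, NA, NA), # missing 0.15 > 0.1 -> drop
    c(rep(1L, 10), rep(0L, 10)),         # clean -> keep
    c(rep(1L, 16), rep(2L, 4)))          # het 0.8 (not > 0.8) -> keep
  sites <- data.frame(chrom = "chr1", pos = (1:5) * 100L, ref = "A",
                      alt = c("T", "T", "T", "T", "T,G"),
                      multiallelic = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  gm <- GenotypeMatrix(sprintf("s%d", 1:n), sites, calls)
  out <- filterMarkers(gm, markerFilterConfig())
  expect_equal(siteInfo(out)$pos, 400L)   # site5 dropped as triallelic
  # depth trimming removes the extreme tails
  nn <- 10
  calls2 <- matrix(1L, nn, 10); calls2[1:5, ] <- 0L
  sites2 <- data.frame(chrom = "chr1", pos = (1:10) * 10L, ref = "A", alt = "T",
                       multiallelic = FALSE)
  depth <- matrix(rep(c(1, 20, 20, 20, 20, 20, 20, 20, 20, 500),
                      each = nn), nn, 10)
  gm2 <- GenotypeMatrix(sprintf("s%d", 1:nn), sites2, calls2, depth)
  out2 <- filterMarkers(gm2, markerFilterConfig(depth_trim_fraction = 0.1))
  expect_false(any(siteInfo(out2)$pos %in% c(10L, 100L)))
})

test_that("phase clustering splits correlated and anti-correlated markers", {
  set.seed(3)
  n <- 60
  h <- sample(0:1, n, replace = TRUE)
  x <- cbind(m1 = h, m2 = h, m3 = 1L - h)
  mk <- data.frame(marker = c("m1", "m2", "m3"), chrom = "chr1",
                   pos_bp = c(100L, 200L, 300L))
  org <- c(m1 = "Mahan", m2 = "Mahan", m3 = "Major")
  cg <- phaseTestcross(x, mk, org, origin_levels = c("Mahan", "Major"))
  ph <- markerInfo(cg)$phase
  expect_equal(ph, c("Mahan-like", "Mahan-like", "Major-like"))
  # haplotype coding is consistent: all three columns now identical
  a <- crossGeno(cg)
  expect_true(all(a[, 1] == a[, 2] & a[, 2] == a[, 3]))
  expect_error(phaseTestcross(x[, 1, drop = FALSE], mk[1, ], org[1],
                              origin_levels = c("Mahan", "Major")),
               "fewer than 2")
})

test_that("phasing recovers simulated haplotypes via the parental table", {
  sim <- simulateF1Cross(crossSimConfig(n_progeny = 120, n_markers = 90,
                                        chrom_lengths_cM = c(70, 70),
                                        qtl = list(chrom = 1, pos_cM = 30,
                                                   effect = 0), seed = 19))
  cg <- phaseTestcross(sim$x, sim$markers, sim$parental_origin,
                       origin_levels = c("Mahan", "Major"))
  mk <- markerInfo(cg)
  hap <- sim$truth$haplotypes[, match(mk$marker, sim$markers$marker)]
  expect_equal(unname(crossGeno(cg)), unname((hap == 1) * 1L))
  # phase labels match the planted alt-allele origins
  planted <- c("Mahan-like", "Major-like")[
    sim$truth$phase[match(mk$marker, sim$markers$marker)]]
  expect_equal(mk$phase, planted)
})

test_that("marker binning keeps the most locally concordant marker per phase-bin", {
  set.seed(7)
  n <- 80
  h <- sample(0:1, n, replace = TRUE)
  x <- matrix(rep(h, 12), n, 12)
  colnames(x) <- sprintf("m%02d", 1:12)
  # marker m06 discordant with its neighbourhood; m05 concordant, same bin
  x[, 6] <- sample(0:1, n, replace = TRUE)
  pos <- c(1e3, 6e3, 11e3, 16e3, 21e3, 22e3, 30e3, 35e3, 40e3, 45e3, 50e3, 55e3)
  mk <- data.frame(marker = colnames(x), chrom = "chr1", pos_bp = as.integer(pos),
                   cM = NA_real_, phase = "Mahan-like")
  cg <- CrossGenotypes(x, mk, sprintf("p%d", 1:n))
  out <- binMarkers(cg, bin_size = 25000, local_window = 3)
  kept <- markerInfo(out)$marker
  expect_false("m06" %in% kept)      # discordant marker dropped
  expect_true(all(c("m07", "m11") %in% kept))  # other bins keep their markers
  # agreement ties among the concordant markers keep the lower coordinate
  expect_true("m01" %in% kept)
  expect_false("m02" %in% kept)
  expect_equal(length(kept), 3)      # one marker per (phase, bin)
})

test_that("map estimation inverts the Kosambi function with error correction", {
  n <- 100
  g1 <- rep(c(0L, 1L), each = n / 2)
  g2 <- g1; g2[1:25] <- 1L - g2[1:25]          # exactly 25% recombinants
  x <- cbind(mA = g1, mB = g2)
  mk <- data.frame(marker = c("mA", "mB"), chrom = "chr1",
                   pos_bp = c(1L, 1000L), cM = NA_real_, phase = "Mahan-like")
  cg <- estimateMap(CrossGenotypes(x, mk, sprintf("p%d", 1:n)), error_prob = 0)
  expect_equal(markerInfo(cg)$cM, c(0, 25 * log(3)), tolerance = 1e-9)
  # identical columns, zero error -> zero distance
  cg0 <- estimateMap(CrossGenotypes(cbind(mA = g1, mB = g1), mk,
                                    sprintf("p%d", 1:n)), error_prob = 0)
  expect_equal(markerInfo(cg0)$cM, c(0, 0))
  # with nonzero error_prob the same observed mismatch yields a shorter map
  cge <- estimateMap(CrossGenotypes(x, mk, sprintf("p%d", 1:n)),
                     error_prob = 0.0165)
  expect_lt(markerInfo(cge)$cM[2], 25 * log(3))
})

test_that("estimated map length approaches simulated truth with many progeny", {
  sim <- simulateF1Cross(crossSimConfig(n_progeny = 1000, n_markers = 80,
                                        chrom_lengths_cM = c(90, 90),
                                        qtl = list(chrom = 1, pos_cM = 45,
                                                   effect = 0), seed = 29))
  cg <- estimateMap(phaseTestcross(sim$x, sim$markers, sim$parental_origin,
                                   origin_levels = c("Mahan", "Major")),
                    error_prob = 0)
  mk <- markerInfo(cg)
  for (ch in unique(mk$chrom)) {
    est_len <- max(mk$cM[mk$chrom == ch])
    true_len <- diff(range(sim$markers$cM_true[sim$markers$chrom == ch]))
    expect_lt(abs(est_len - true_len) / true_len, 0.10)
  }
})

test_that("LOD scans find planted QTL at the expected magnitude", {
  sim <- simulateF1Cross(crossSimConfig(n_progeny = 143, n_markers = 120,
                                        chrom_lengths_cM = c(80, 80, 80),
                                        qtl = list(chrom = 2, pos_cM = 40,
                                                   effect = 0.5), seed = 3))
  cg <- estimateMap(phaseTestcross(sim$x, sim$markers, sim$parental_origin,
                                   origin_levels = c("Mahan", "Major")),
                    error_prob = 0)
  sc <- scanConfig(step = 1, n_permutations = 500, seed = 42)
  scan <- scanLod(cg, sim$phenotype, sc)
  expect_equal(scan$peak$chrom, "chr2")
  # closed-form expectation for R^2 = 0.5: (n/2) log10(2) ~ 21.5, +-25%
  expect_gt(scan$peak$lod, 21.5 * 0.75 * 0.8)  # LOCO shrinks the peak somewhat
  expect_lt(scan$peak$lod, 21.5 * 1.25)
  # LOD is invariant to affine phenotype transforms
  scan2 <- scanLod(cg, 3.7 * sim$phenotype - 11, sc)
  expect_equal(scan2$profile$lod, scan$profile$lod, tolerance = 1e-6)
  expect_error(scanLod(cg, rep(1, 143), sc), "constant")
  # a marker orthogonal to the phenotype scores ~0 without kinship
  set.seed(99)
  n <- 143
  x <- cbind(mA = sample(0:1, n, TRUE), mB = sample(0:1, n, TRUE))
  mk <- data.frame(marker = c("mA", "mB"), chrom = "chr1",
                   pos_bp = c(1L, 2000000L), cM = c(0, 50), phase = "Mahan-like")
  cgo <- CrossGenotypes(x, mk, sprintf("p%d", 1:n))
  y <- rnorm(n)
  sco <- scanLod(cgo, y, scanConfig(step = 50, kinship = "none"))
  at_marker <- sco$profile$lod[sco$profile$cM %in% c(0, 50)]
  expect_true(all(at_marker < 1.5))
})

test_that("permutation thresholds are reproducible and control type-I error", {
  sim <- simulateF1Cross(crossSimConfig(n_progeny = 143, n_markers = 100,
                                        chrom_lengths_cM = c(80, 80),
                                        qtl = list(chrom = 1, pos_cM = 40,
                                                   effect = 0), seed = 31))
  cg <- estimateMap(phaseTestcross(sim$x, sim$markers, sim$parental_origin,
                                   origin_levels = c("Mahan", "Major")),
                    error_prob = 0)
  sc <- scanConfig(step = 1, n_permutations = 200, seed = 7)
  t1 <- permutationThreshold(cg, sim$phenotype, sc)
  t2 <- permutationThreshold(cg, sim$phenotype, sc)
  expect_equal(t1$threshold, t2$threshold)
  expect_error(permutationThreshold(cg, sim$phenotype,
                                    scanConfig(n_permutations = 0)), "> 0")
  expect_warning(permutationThreshold(cg, sim$phenotype,
                                      scanConfig(n_permutations = 50, seed = 1)),
                 "100")
  # null phenotypes stay below the threshold most of the time
  hits <- 0
  for (seed in 1:20) {
    simn <- simulateF1Cross(crossSimConfig(n_progeny = 143, n_markers = 100,
                                           chrom_lengths_cM = c(80, 80),
                                           qtl = list(chrom = 1, pos_cM = 40,
                                                      effect = 0), seed = seed))
    cgn <- estimateMap(phaseTestcross(simn$x, simn$markers,
                                      simn$parental_origin,
                                      origin_levels = c("Mahan", "Major")),
                       error_prob = 0)
    scn <- scanConfig(step = 2, n_permutations = 200, seed = seed)
    peak <- scanLod(cgn, simn$phenotype, scn)$peak$lod
    thr <- permutationThreshold(cgn, simn$phenotype, scn)$threshold
    if (peak >= thr) hits <- hits + 1
  }
  expect_lte(hits, 4)  # ~5% expected; binomial slack for 20 replicates
})

test_that("Bayes credible intervals match brute-force mass accumulation", {
  mkprof <- function(lod) data.frame(chrom = "chr1", cM = seq_along(lod),
                                     pos_bp = seq_along(lod) * 1e5, lod = lod)
  # delta-like profile: interval collapses to the peak
  d <- rep(0, 11); d[6] <- 8
  bi <- bayesInterval(mkprof(d), 0.95)
  expect_equal(bi$cM_lo, 6); expect_equal(bi$cM_hi, 6)
  # flat profile: whole chromosome
  bf <- bayesInterval(mkprof(rep(1, 11)), 0.95)
  expect_equal(c(bf$cM_lo, bf$cM_hi), c(1, 11))
  # triangular profile equals the oracle
  tri <- c(0, 1, 2, 3, 4, 5, 4, 3, 2, 1, 0)
  bt <- bayesInterval(mkprof(tri), 0.95)
  orc <- oracle_bayes(tri, 0.95)
  expect_equal(bt$cM_lo, orc$i)
  expect_equal(bt$cM_hi, orc$j)
  expect_gte(bt$mass, 0.95)
  # random profiles: minimality and peak containment
  set.seed(4)
  for (rep in 1:10) {
    lod <- runif(15, 0, 4)
    b <- bayesInterval(mkprof(lod), 0.9)
    o <- oracle_bayes(lod, 0.9)
    expect_equal(b$cM_hi - b$cM_lo, o$j - o$i)
    pk <- which.max(lod)
    expect_true(b$cM_lo <= pk && pk <= b$cM_hi)
  }
})

test_that("candidate ranking prioritises haplotype-divergent and PAV genes", {
  comp <- data.frame(
    pan_id = sprintf("OG%d", 1:4), pan_chrom = "chr16", pan_position = 1:4,
    primary_gene = sprintf("P%d", 1:4),
    class = c("both", "both", "primary_only_with_alt_contig",
              "primary_only_no_alt_contig"),
    alt_gene = c("A1", "A2", NA, NA),
    identity_pct = c(97.5, 99.5, NA, NA), stringsAsFactors = FALSE)
  proj <- list(comparisons = comp)
  out <- rankCandidates(proj, sprintf("P%d", 1:4), interval_alt_genes = "A9",
                        tags = c(P1 = "LRR"))
  expect_equal(out$priority[out$gene == "P1"], "high")   # identity < 98
  expect_equal(out$priority[out$gene == "P2"], "low")    # identity 99.5
  expect_equal(out$priority[out$gene == "P3"], "high")   # PAV with contig
  expect_equal(out$priority[out$gene == "P4"], "low")    # homozygous region
  expect_equal(out$priority[out$gene == "A9"], "high")   # alt-only
  expect_equal(out$tag[out$gene == "P1"], "LRR")
})
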
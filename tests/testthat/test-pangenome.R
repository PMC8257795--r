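# Small hand-built two/three-genome panels used across these tests.

# genomes ref + g2, 30 collinear genes; optionally a translocated extra pair
toy_panel <- function(translocated = FALSE) {
  mk_genes <- function(gnm, ids, chrom, ranks) {
    data.frame(gene_id = ids, genome = gnm, chrom = chrom,
               start = ranks * 1000L, end = ranks * 1000L + 500L,
               strand = "+", rank = ranks, length = 500L,
               stringsAsFactors = FALSE)
  }
  ref <- mk_genes("ref", sprintf("R%02d", 0:29), "chr1", 0:29)
  g2 <- mk_genes("g2", sprintf("Q%02d", 0:29), "chr1", 0:29)
  hits <- do.call(rbind, lapply(0:29, function(i) {
    data.frame(query_gene = sprintf("R%02d", i), target_gene = sprintf("Q%02d", i),
               query_genome = "ref", target_genome = "g2", bitscore = 100,
               stringsAsFactors = FALSE)
  }))
  hits <- rbind(hits, stats::setNames(
    hits[, c(2, 1, 4, 3, 5)], names(hits)))
  if (translocated) {
    # one isolated pair far from any block on another chromosome of g2
    ref <- rbind(ref, mk_genes("ref", "RX", "chr2", 0L))
    g2 <- rbind(g2, mk_genes("g2", "QX", "chr9", 0L))
    hits <- rbind(hits,
      data.frame(query_gene = c("RX", "QX"), target_gene = c("QX", "RX"),
                 query_genome = c("ref", "g2"), target_genome = c("g2", "ref"),
                 bitscore = 100, stringsAsFactors = FALSE))
  }
  list(genes = rbind(ref, g2), hits = hits)
}

test_that("synteny constraint keeps block hits and removes isolated translocations", {
  tp <- toy_panel(translocated = TRUE)
  blocks <- syntenicBlocks(tp$genes, tp$hits)
  expect_true(nrow(blocks) >= 1)
  kept <- constrainToSynteny(tp$hits, blocks, tp$genes)
  expect_true(any(kept$query_gene == "R05"))          # hit inside a block
  expect_false(any(kept$query_gene == "RX"))          # isolated pair removed
  expect_false(any(kept$target_gene == "RX"))
})

test_that("synteny-constrained orthogroups equal simulator truth without noise", {
  cfg <- pangenomeSimConfig(n_chroms = 2, genes_per_chrom = 100, n_genomes = 3,
                            wgd = FALSE, n_rearrangements = 0, pav_rate = 0.05,
                            private_rate = 0.02, tandem_rate = 0, seed = 31)
  sim <- simulatePangenome(cfg, sequences = FALSE)
  blocks <- syntenicBlocks(sim$genes, sim$hits)
  kept <- constrainToSynteny(sim$hits, blocks, sim$genes)
  og <- clusterOrthogroups(kept, sim$genes)
  truth <- sim$truth$orthogroups
  # same partition: every truth orthogroup maps to exactly one inferred one
  key <- stats::setNames(og$og_id, paste(og$genome, og$gene_id))
  for (o in unique(truth$og_id)) {
    rows <- truth[truth$og_id == o, ]
    inferred <- unique(key[paste(rows$genome, rows$gene_id)])
    expect_length(inferred, 1)
  }
  expect_equal(length(unique(og$og_id)), length(unique(truth$og_id)))
})

test_that("tandem arrays condense within chromosomes with the stated tie rules", {
  genes <- data.frame(
    gene_id = c("a1", "a2", "a3", "b1"),
    genome = "g", chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(0L, 1000L, 2000L, 0L), end = c(500L, 1500L, 2500L, 800L),
    strand = "+", rank = c(0L, 1L, 2L, 0L),
    length = c(500L, 500L, 800L, 800L), stringsAsFactors = FALSE)
  og <- data.frame(og_id = "OG1", genome = "g",
                   gene_id = c("a1", "a2", "a3", "b1"))
  hits <- data.frame(query_gene = character(), target_gene = character(),
                     query_genome = character(), target_genome = character(),
                     bitscore = numeric())
  cond <- condenseTandemArrays(og, genes, hits, max_gap = 20)
  # three adjacent same-chromosome genes form one array; chr2 member another
  expect_equal(length(unique(cond$array_id[cond$chrom == "chr1"])), 1)
  expect_equal(length(unique(cond$array_id)), 2)
  # bitscore tie (all 0) -> representative closest to the median rank
  rep1 <- cond$gene_id[cond$chrom == "chr1" & cond$is_representative]
  expect_equal(rep1, "a2")
})

test_that("orthogroup placement follows the hierarchical reference rules", {
  # single-copy in reference at rank 42
  genes <- data.frame(
    gene_id = c("r42", "q1"), genome = c("ref", "g2"),
    chrom = "chr1", start = c(42000L, 0L), end = c(42500L, 500L),
    strand = "+", rank = c(42L, 0L), length = 500L, stringsAsFactors = FALSE)
  og <- data.frame(og_id = "OG1", genome = c("ref", "g2"),
                   gene_id = c("r42", "q1"))
  hits <- data.frame(query_gene = "r42", target_gene = "q1",
                     query_genome = "ref", target_genome = "g2", bitscore = 99)
  pg <- placeOrthogroups(og, genes, hits, emptyBlocks <- syntenicBlocks(genes, hits),
                         reference = "ref")
  expect_equal(panEntries(pg)$pan_position, 42)
  expect_equal(panEntries(pg)$pan_chrom, "chr1")
})

test_that("reference-absent orthogroups take the mean interpolated position", {
  # ref chr1 genes A00..A29 at ranks 0..29; g2 misses A10's ortholog and
  # instead carries X2 at that slot; g3 likewise at slot 12 -> interpolated
  # positions 10 and 12, mean 11
  mk <- function(gnm, ids, ranks) data.frame(
    gene_id = ids, genome = gnm, chrom = "chr1", start = ranks * 1000L,
    end = ranks * 1000L + 500L, strand = "+", rank = ranks, length = 500L,
    stringsAsFactors = FALSE)
  ref <- mk("ref", sprintf("A%02d", 0:29), 0:29)
  ids2 <- sprintf("B%02d", 0:29); ids2[11] <- "X2"    # slot of rank 10
  g2 <- mk("g2", ids2, 0:29)
  ids3 <- sprintf("C%02d", 0:29); ids3[13] <- "X3"    # slot of rank 12
  g3 <- mk("g3", ids3, 0:29)
  genes <- rbind(ref, g2, g3)
  both_dirs <- function(h) rbind(h, stats::setNames(h[, c(2, 1, 4, 3, 5)], names(h)))
  hp <- function(q, t, qg, tg) data.frame(
    query_gene = q, target_gene = t, query_genome = qg, target_genome = tg,
    bitscore = 100, stringsAsFactors = FALSE)
  keep2 <- setdiff(0:29, 10); keep3 <- setdiff(0:29, 12)
  keep23 <- intersect(keep2, keep3)
  hits <- rbind(
    both_dirs(hp(sprintf("A%02d", keep2), sprintf("B%02d", keep2), "ref", "g2")),
    both_dirs(hp(sprintf("A%02d", keep3), sprintf("C%02d", keep3), "ref", "g3")),
    both_dirs(hp(sprintf("B%02d", keep23), sprintf("C%02d", keep23), "g2", "g3")),
    both_dirs(hp("X2", "X3", "g2", "g3")))
  pg <- buildPangenome(genes, hits, reference = "ref")
  ent <- panEntries(pg)
  x_entry <- which(vapply(pg@members[["g2"]], function(m) "X2" %in% m, logical(1)))
  expect_length(x_entry, 1)
  expect_equal(ent$pan_position[x_entry], 11)
  # placement order is total and deterministic under permutation
  perm <- sample(nrow(genes))
  pg2 <- buildPangenome(genes[perm, ], hits[sample(nrow(hits)), ], reference = "ref")
  expect_identical(panEntries(pg2), ent)
})

test_that("multi-copy reference orthogroups anchor at the best summed bitscore", {
  genes <- data.frame(
    gene_id = c("rA", "rB", "q1"), genome = c("ref", "ref", "g2"),
    chrom = c("chr1", "chr2", "chr1"), start = c(5000L, 7000L, 0L),
    end = c(5500L, 7500L, 500L), strand = "+", rank = c(5L, 7L, 0L),
    length = 500L, stringsAsFactors = FALSE)
  og <- data.frame(og_id = "OG1", genome = c("ref", "ref", "g2"),
                   gene_id = c("rA", "rB", "q1"))
  # within-genome bitscores: rA sums 900, rB 700
  hits <- data.frame(
    query_gene = c("rA", "rB"), target_gene = c("rB", "rA"),
    query_genome = "ref", target_genome = "ref",
    bitscore = c(900, 700), stringsAsFactors = FALSE)
  pg <- placeOrthogroups(og, genes, hits, syntenicBlocks(genes, hits),
                         reference = "ref")
  expect_equal(panEntries(pg)$pan_position, 5)
  expect_equal(panEntries(pg)$pan_chrom, "chr1")
})

test_that("PAV flags and summary follow presence patterns exactly", {
  cfg <- pangenomeSimConfig(n_chroms = 2, genes_per_chrom = 120, n_genomes = 3,
                            wgd = FALSE, pav_rate = 0.08, private_rate = 0.03,
                            tandem_rate = 0.03, seed = 11)
  sim <- simulatePangenome(cfg, sequences = FALSE)
  pg <- buildPangenome(sim$genes, sim$hits, reference = "genome1")
  pav <- pavTable(pg)
  m <- pav$matrix
  expect_equal(pav$flags$complete, unname(rowSums(m) == ncol(m)))
  expect_true(all(rowSums(m[!is.na(pav$flags$private_to), , drop = FALSE]) == 1))
  expect_equal(pav$summary$n_complete + pav$summary$n_incomplete,
               pav$summary$n_orthogroups)
  # recovers the simulator's truth matrix exactly at zero noise
  truth <- sim$truth$pav
  g2e <- new.env()
  for (g in panGenomes(pg)) {
    mem <- pg@members[[g]]
    for (i in seq_along(mem)) for (gid in mem[[i]]) assign(gid, i, envir = g2e)
  }
  ok <- TRUE
  for (o in rownames(truth)) {
    gids <- sim$truth$orthogroups$gene_id[sim$truth$orthogroups$og_id == o]
    idx <- unique(vapply(gids, function(g) get(g, envir = g2e), integer(1)))
    ok <- ok && length(idx) == 1 &&
      identical(unname(panPresence(pg)[idx, ]), unname(truth[o, ]))
  }
  expect_true(ok)
})

test_that("absence runs require five consecutive absent entries", {
  pres <- matrix(TRUE, 20, 2, dimnames = list(NULL, c("a", "b")))
  pres[3:7, "b"] <- FALSE    # run of 5
  pres[10:13, "b"] <- FALSE  # run of 4 (below threshold)
  pres[15, "b"] <- FALSE; pres[17:21 - 1, "b"] <- c(FALSE, FALSE, FALSE, FALSE, FALSE)
  pres <- pres[1:20, ]
  ent <- data.frame(pan_id = sprintf("OG%02d", 1:20), pan_chrom = "chr1",
                    pan_position = 1:20, stringsAsFactors = FALSE)
  members <- list(
    a = lapply(1:20, function(i) "x"),
    b = lapply(1:20, function(i) if (pres[i, "b"]) "y" else character()))
  members$a <- lapply(1:20, function(i) if (pres[i, "a"]) "x" else character())
  rep_m <- ifelse(pres, "g", NA_character_)
  pg <- new("Pangenome", entries = ent, genomes = c("a", "b"),
            presence = pres, members = members, representative = rep_m,
            reference = "a", outgroup = NA_character_)
  runs <- absenceRuns(pg, "b", min_run = 5)
  expect_equal(nrow(runs), 2)
  expect_equal(runs$run_length[1], 5)
  expect_equal(runs$start_index[1], 3)
  expect_equal(absenceRuns(pg, "a", 5)$run_length, integer(0))
})

test_that("absence classification thresholds and monotonicity hold", {
  expect_error(classifyAbsence("", "ACGT"), "empty CDS")
  cds <- paste(rep("ACGTTGCA", 25), collapse = "")
  region <- paste0("TTTTT", cds, "AAAAA")
  r <- classifyAbsence(cds, region)
  expect_equal(r$coverage_pct, 100)
  expect_equal(r$identity_pct, 100)
  expect_equal(r$category, "very_similar")
  # diverged: mutate ~20% of the copy in the region
  set.seed(5)
  ch <- strsplit(cds, "")[[1]]
  mut <- ch; idx <- sample(length(ch), 40)
  mut[idx] <- vapply(ch[idx], function(b) setdiff(c("A", "C", "G", "T"), b)[1], "")
  r2 <- classifyAbsence(cds, paste(mut, collapse = ""))
  expect_true(r2$identity_pct < 95)
  expect_equal(r2$category, "diverged")
  # absent: only half the CDS present even though identity is high
  r3 <- classifyAbsence(cds, substr(cds, 1, 100))
  expect_true(r3$coverage_pct < 75)
  expect_equal(r3$category, "absent")
  # category is monotone in (coverage, identity) by construction of the rules
  cat_of <- function(cov, id) {
    if (cov > 99 && id >= 95) "very_similar"
    else if (cov >= 75 && id >= 75) "diverged" else "absent"
  }
  lvl <- c(absent = 1, diverged = 2, very_similar = 3)
  for (cov in c(50, 75, 90, 99, 99.5, 100)) for (id in c(50, 75, 90, 95, 100)) {
    expect_gte(lvl[cat_of(cov + 0.4, id)], lvl[cat_of(cov, id)])
    expect_gte(lvl[cat_of(cov, min(id + 5, 100))], lvl[cat_of(cov, id)])
  }
})

test_that("interval private enrichment reports fraction, odds ratio and exact p", {
  flags <- data.frame(
    pan_id = sprintf("OG%04d", 1:1096),
    complete = FALSE, incomplete = TRUE,
    private_to = c(rep("lakota", 8), rep(NA, 38), rep("lakota", 50),
                   rep(NA, 1000)),
    stringsAsFactors = FALSE)
  pav <- list(flags = flags)
  interval <- flags$pan_id[1:46]
  res <- intervalPrivateEnrichment(pav, interval, "lakota")
  expect_equal(res$private_fraction_pct, 17.4)
  expect_equal(res$p_value, oracle_fisher_p(8, 38, 50, 1000), tolerance = 1e-12)
  # 0 private in interval -> odds ratio 0
  res0 <- intervalPrivateEnrichment(pav, flags$pan_id[9:46], "lakota")
  expect_equal(res0$odds_ratio, 0)
  expect_error(intervalPrivateEnrichment(pav, "nope", "lakota"), "disjoint")
  expect_error(intervalPrivateEnrichment(pav, character(), "lakota"), "empty")
})

test_that("haplotype identity penalises internal gaps and excludes terminal ones", {
  expect_equal(proteinIdentityPct("ACDEFG", "ACDFG"), 100 * 5 / 6,
               tolerance = 1e-9)
  expect_equal(proteinIdentityPct("MKVLW", "MKVLW"), 100)
})

test_that("alt-haplotype projection classifies entries and places contigs", {
  # pan-genome with 6 reference entries at positions 0..5
  ent <- data.frame(pan_id = sprintf("OG%d", 1:6), pan_chrom = "chr1",
                    pan_position = 0:5, stringsAsFactors = FALSE)
  pres <- matrix(TRUE, 6, 1, dimnames = list(NULL, "ref"))
  members <- list(ref = lapply(sprintf("P%d", 1:6), identity))
  rep_m <- matrix(sprintf("P%d", 1:6), 6, 1, dimnames = list(NULL, "ref"))
  pg <- new("Pangenome", entries = ent, genomes = "ref", presence = pres,
            members = members, representative = rep_m, reference = "ref",
            outgroup = NA_character_)
  alt_genes <- data.frame(gene_id = c("A1", "A2", "A5"), genome = "alt",
                          chrom = "ctg1", start = c(0L, 1000L, 2000L),
                          end = c(500L, 1500L, 2500L), strand = "+",
                          rank = 0:2, length = 500L, stringsAsFactors = FALSE)
  # orthologs: P1<->A1, P3<->A2; A5 has no primary ortholog
  hits <- data.frame(
    query_gene = c("P1", "A1", "P3", "A2", "A5"),
    target_gene = c("A1", "P1", "A2", "P3", "P2"),
    query_genome = c("ref", "alt", "ref", "alt", "alt"),
    target_genome = c("alt", "ref", "alt", "ref", "ref"),
    bitscore = c(100, 100, 90, 90, 30), stringsAsFactors = FALSE)
  prot <- Biostrings::AAStringSet(c(P1 = "MKVLW", P3 = "MACDEFG"))
  altp <- Biostrings::AAStringSet(c(A1 = "MKVLW", A2 = "MACDFG"))
  proj <- projectToAltHaplotype(pg, alt_genes, hits, prot, altp, "ref")
  cmp <- proj$comparisons
  expect_equal(cmp$class[cmp$primary_gene == "P1"], "both")
  expect_equal(cmp$identity_pct[cmp$primary_gene == "P1"], 100)
  expect_equal(cmp$class[cmp$primary_gene == "P3"], "both")
  # P2 lies between the contig's members (positions 0 and 2): covered PAV
  expect_equal(cmp$class[cmp$primary_gene == "P2"], "primary_only_with_alt_contig")
  # P6 at position 5 is outside the contig span: homozygous-region class
  expect_equal(cmp$class[cmp$primary_gene == "P6"], "primary_only_no_alt_contig")
  expect_equal(proj$alt_only$alt_gene, "A5")
  expect_equal(proj$contigs$midpoint, 1)   # members at 0 and 2
})
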
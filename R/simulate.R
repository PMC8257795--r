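SENSE_CODONS <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' Pan-genome simulation configuration
#'
#' Defaults emulate a four-genome panel descended from a whole-genome
#' duplication: `n_chroms` ancestral chromosomes (doubled to homeolog
#' pairs when `wgd`), per-gene loss (`pav_rate`), private gene gain
#' (`private_rate`) and tandem duplication (`tandem_rate`) per genome.
#'
#' @param n_chroms ancestral chromosome number (post-WGD genomes carry
#'   2 x n_chroms chromosomes).
#' @param genes_per_chrom ancestral genes per chromosome.
#' @param n_genomes number of genomes.
#' @param wgd duplicate the ancestral genome into homeolog pairs.
#' @param n_rearrangements reciprocal-translocation/inversion events
#'   planted between homeolog copies (shared by all genomes).
#' @param pav_rate per-gene per-genome loss probability (< 1).
#' @param private_rate per-position probability of gaining a private gene.
#' @param tandem_rate per-gene tandem duplication probability.
#' @param prop_inversions fraction of planted events that are inversions
#'   (the rest are reciprocal tail translocations).
#' @param seed integer seed.
#' @return list of simulation parameters.
#' @export
pangenomeSimConfig <- function(n_chroms = 4, genes_per_chrom = 250,
                               n_genomes = 4, wgd = TRUE,
                               n_rearrangements = 0, pav_rate = 0.05,
                               private_rate = 0.02, tandem_rate = 0.02,
                               prop_inversions = 0.5, seed = 1) {
  stopifnot(n_chroms >= 1, genes_per_chrom >= 30, n_genomes >= 1,
            pav_rate >= 0, private_rate >= 0, private_rate <= 1,
            tandem_rate >= 0, tandem_rate <= 1, n_rearrangements >= 0)
  if (pav_rate >= 1) stop("pav_rate = 1 leaves no shared genes")
  list(n_chroms = n_chroms, genes_per_chrom = genes_per_chrom,
       n_genomes = n_genomes, wgd = wgd,
       n_rearrangements = n_rearrangements, pav_rate = pav_rate,
       private_rate = private_rate, tandem_rate = tandem_rate,
       prop_inversions = prop_inversions, seed = seed)
}

mutate_cds <- function(codons, d, sense) {
  if (d <= 0) return(codons)
  L <- length(codons) * 3L
  n_mut <- stats::rbinom(1, L, d)
  if (n_mut == 0) return(codons)
  pos <- sample.int(L, n_mut)
  for (p in pos) {
    ci <- (p - 1L) %/% 3L + 1L
    off <- (p - 1L) %% 3L + 1L
    chars <- strsplit(codons[ci], "")[[1]]
    for (nt in sample(setdiff(NTS, chars[off]))) {
      alt <- chars; alt[off] <- nt
      altc <- paste(alt, collapse = "")
      if (altc %in% sense) { codons[ci] <- altc; break }
    }
  }
  codons
}

#' Simulate an annotated multi-genome pan-genome panel
#'
#' Generates an ancestral gene order, duplicates it under a WGD into
#' homeolog chromosome pairs, plants `n_rearrangements` events (segment
#' inversions and reciprocal tail translocations between homeolog copies,
#' shared by all genomes), then applies per-genome gene loss, tandem
#' duplication and private gene gain. Similarity hits are emitted between
#' all true homologs with bitscores decreasing in the planted divergence;
#' protein and CDS sequences are optional. Ground truth (orthogroup
#' membership, PAV matrix, planted events and the extra homeolog blocks
#' they create) is returned for recovery tests.
#'
#' @param cfg a [pangenomeSimConfig()] list.
#' @param sequences also simulate CDS/protein sequences (default TRUE).
#' @return list: `genes` (combined gene-model table), `hits`,
#'   `cds`/`proteins` (named `DNAStringSet`/`AAStringSet`, or NULL),
#'   `truth` (list: `orthogroups`, `pav`, `events`,
#'   `expected_extra_blocks`, `config`).
#' @export
simulatePangenome <- function(cfg = pangenomeSimConfig(), sequences = TRUE) {
  set.seed(cfg$seed)
  n_ch <- cfg$n_chroms; gpc <- cfg$genes_per_chrom
  og_ids <- sprintf("OG%05d", seq_len(n_ch * gpc))
  anc_chrom <- rep(seq_len(n_ch), each = gpc)
  # post-WGD ancestral layout: chrom -> ordered og ids (+ copy label)
  layout <- list()
  for (c in seq_len(n_ch)) {
    ogs <- og_ids[anc_chrom == c]
    layout[[sprintf("chr%02d", c)]] <- data.frame(
      og = ogs, copy = "A", stringsAsFactors = FALSE)
    if (cfg$wgd)
      layout[[sprintf("chr%02d", c + n_ch)]] <- data.frame(
        og = ogs, copy = "B", stringsAsFactors = FALSE)
  }
  # planted rearrangements on the B copies (fresh chromosomes per event so
  # each event contributes exactly two extra homeolog blocks)
  events <- list()
  if (cfg$n_rearrangements > 0) {
    if (!cfg$wgd) stop("rearrangements require wgd = TRUE")
    n_inv <- round(cfg$n_rearrangements * cfg$prop_inversions)
    types <- c(rep("inversion", n_inv),
               rep("translocation", cfg$n_rearrangements - n_inv))
    needed <- sum(types == "inversion") + 2 * sum(types == "translocation")
    if (needed > n_ch)
      stop("too many rearrangements for ", n_ch, " chromosome pairs")
    pool <- sample(sprintf("chr%02d", seq_len(n_ch) + n_ch))
    for (ty in types) {
      if (ty == "inversion") {
        if (gpc < 210)
          stop("inversion events need genes_per_chrom >= 210 so the ",
               "inverted segment exceeds twice the chaining gap; use more ",
               "genes or prop_inversions = 0")
        ch <- pool[1]; pool <- pool[-1]
        quarter <- gpc %/% 4
        seg <- (quarter + 1):(quarter + gpc %/% 2)
        layout[[ch]][seg, ] <- layout[[ch]][rev(seg), ]
        events[[length(events) + 1L]] <-
          list(type = "inversion", chrom = ch, span = range(seg))
      } else {
        ch1 <- pool[1]; ch2 <- pool[2]; pool <- pool[-(1:2)]
        cut <- gpc %/% 2
        tail1 <- layout[[ch1]][(cut + 1):gpc, ]
        tail2 <- layout[[ch2]][(cut + 1):gpc, ]
        layout[[ch1]] <- rbind(layout[[ch1]][1:cut, ], tail2)
        layout[[ch2]] <- rbind(layout[[ch2]][1:cut, ], tail1)
        events[[length(events) + 1L]] <-
          list(type = "translocation", chroms = c(ch1, ch2), cut = cut)
      }
    }
  }
  genomes <- sprintf("genome%d", seq_len(cfg$n_genomes))
  depth <- stats::setNames(0.002 * seq_len(cfg$n_genomes), genomes)
  wgd_extra <- 0.06
  gene_rows <- list(); truth_rows <- list()
  priv_counter <- 0L
  for (g in genomes) {
    for (ch in names(layout)) {
      lay <- layout[[ch]]
      keep <- stats::runif(nrow(lay)) >= cfg$pav_rate
      entries <- list()
      for (i in seq_len(nrow(lay))) {
        if (keep[i]) {
          entries[[length(entries) + 1L]] <-
            list(og = lay$og[i], copy = lay$copy[i], private = FALSE)
          if (stats::runif(1) < cfg$tandem_rate)
            entries[[length(entries) + 1L]] <-
              list(og = lay$og[i], copy = lay$copy[i], private = FALSE)
        }
        if (stats::runif(1) < cfg$private_rate) {
          priv_counter <- priv_counter + 1L
          entries[[length(entries) + 1L]] <-
            list(og = sprintf("PG%05d", priv_counter), copy = "P",
                 private = TRUE)
        }
      }
      if (!length(entries)) next
      n_e <- length(entries)
      ids <- sprintf("%s_%s_g%04d", g, ch, seq_len(n_e))
      start <- (seq_len(n_e) - 1L) * 2000L
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        gene_id = ids, genome = g, chrom = ch, start = start,
        end = start + 1200L, strand = "+", rank = seq_len(n_e) - 1L,
        length = 1200L,
        og = vapply(entries, `[[`, character(1), "og"),
        copy = vapply(entries, `[[`, character(1), "copy"),
        stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, gene_rows)
  rownames(genes) <- NULL
  truth_og <- genes[, c("og", "genome", "gene_id", "copy")]
  names(truth_og)[1] <- "og_id"
  all_ogs <- c(og_ids, sprintf("PG%05d", seq_len(priv_counter)))
  pav <- matrix(FALSE, length(all_ogs), length(genomes),
                dimnames = list(all_ogs, genomes))
  tab <- unique(truth_og[, c("og_id", "genome")])
  pav[cbind(tab$og_id, tab$genome)] <- TRUE
  # similarity hits between all same-orthogroup gene pairs
  hits <- NULL
  shared <- genes[!startsWith(genes$og, "PG"), , drop = FALSE]
  by_og <- split(seq_len(nrow(shared)), shared$og)
  hit_list <- lapply(by_og, function(idx) {
    if (length(idx) < 2) return(NULL)
    pr <- expand.grid(i = idx, j = idx)
    pr <- pr[pr$i != pr$j, , drop = FALSE]
    div <- depth[shared$genome[pr$i]] + depth[shared$genome[pr$j]] +
      ifelse(shared$copy[pr$i] != shared$copy[pr$j], wgd_extra, 0)
    data.frame(query_gene = shared$gene_id[pr$i],
               target_gene = shared$gene_id[pr$j],
               query_genome = shared$genome[pr$i],
               target_genome = shared$genome[pr$j],
               bitscore = round(200 * (1 - div), 2),
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hit_list[!vapply(hit_list, is.null, logical(1))])
  rownames(hits) <- NULL
  cds <- proteins <- NULL
  if (sequences) {
    sense <- SENSE_CODONS()
    start_cod <- setdiff(sense, c("TAA", "TAG", "TGA"))
    anc <- lapply(all_ogs, function(o)
      sample(start_cod, 100, replace = TRUE))
    names(anc) <- all_ogs
    seqs <- vapply(seq_len(nrow(genes)), function(i) {
      d <- depth[genes$genome[i]] +
        if (genes$copy[i] == "B") wgd_extra / 2 else 0
      paste(mutate_cds(anc[[genes$og[i]]], d, sense), collapse = "")
    }, character(1))
    cds <- Biostrings::DNAStringSet(stats::setNames(seqs, genes$gene_id))
    proteins <- Biostrings::translate(cds)
  }
  genes_out <- genes[, c("gene_id", "genome", "chrom", "start", "end",
                         "strand", "rank", "length")]
  list(genes = genes_out, hits = hits, cds = cds, proteins = proteins,
       truth = list(orthogroups = truth_og, pav = pav, events = events,
                    expected_extra_blocks = 2L * length(events),
                    config = cfg))
}

#' Simulate a diverged CDS pair with target Ka and Ks
#'
#' Builds a random stop-free ancestral CDS and places
#' round(target_ks x synonymous sites) synonymous and
#' round(target_ka x non-synonymous sites) non-synonymous substitutions at
#' distinct codons (never creating a stop), so the NG86 estimates recover
#' the targets up to sampling noise.
#'
#' @param n_codons CDS length in codons (>= 10).
#' @param target_ka,target_ks target substitution rates per site.
#' @param seed integer seed.
#' @return list `cds_a`, `cds_b` (character), `truth` (targets and placed
#'   substitution counts).
#' @export
simulateCdsEvolution <- function(n_codons, target_ka = 0, target_ks = 0,
                                 seed = 1) {
  if (n_codons < 10) stop("n_codons must be >= 10")
  stopifnot(target_ka >= 0, target_ks >= 0)
  set.seed(seed)
  sense <- SENSE_CODONS()
  gc <- Biostrings::GENETIC_CODE
  codons <- sample(sense, n_codons, replace = TRUE)
  ssites <- ng86_syn_sites()
  S0 <- sum(ssites[codons]); N0 <- 3 * n_codons - S0
  n_s <- round(target_ks * S0); n_n <- round(target_ka * N0)
  # candidate single-nucleotide changes per codon
  cand <- function(ci, synonymous) {
    chars <- strsplit(codons[ci], "")[[1]]
    out <- list()
    for (p in 1:3) for (nt in setdiff(NTS, chars[p])) {
      alt <- chars; alt[p] <- nt
      altc <- paste(alt, collapse = "")
      if (gc[[altc]] == "*") next
      is_syn <- gc[[altc]] == gc[[codons[ci]]]
      if (is_syn == synonymous)
        out[[length(out) + 1L]] <- altc
    }
    out
  }
  mutated <- codons
  used <- logical(n_codons)
  place <- function(n_changes, synonymous) {
    placed <- 0L
    order_ci <- sample.int(n_codons)
    for (ci in order_ci) {
      if (placed >= n_changes) break
      if (used[ci]) next
      opts <- cand(ci, synonymous)
      if (!length(opts)) next
      mutated[ci] <<- opts[[sample.int(length(opts), 1)]]
      used[ci] <<- TRUE
      placed <- placed + 1L
    }
    placed
  }
  placed_s <- place(n_s, TRUE)
  placed_n <- place(n_n, FALSE)
  list(cds_a = paste(codons, collapse = ""),
       cds_b = paste(mutated, collapse = ""),
       truth = list(target_ka = target_ka, target_ks = target_ks,
                    syn_sites = S0, nonsyn_sites = N0,
                    placed_syn = placed_s, placed_nonsyn = placed_n))
}

#' Admixture panel simulation configuration
#'
#' @param n_sources source populations (the last is the recipient
#'   background, i.e. the pecan-like population).
#' @param n_markers markers on one chromosome.
#' @param fst_like_divergence Balding-Nichols drift parameter; 0 makes all
#'   sources identical, values >= 1 plant fixed differences (each marker
#'   diagnostic for one source).
#' @param donor_blocks list of `list(donor = <source index>, span =
#'   <marker index range>)` planted homozygous introgressions shared by
#'   the test genome and its relatives.
#' @param n_relatives relatives carrying the same planted blocks.
#' @param genotyping_error per-allele misread probability.
#' @param recomb_rate morgans per inter-marker interval.
#' @param n_per_source samples genotyped per source population.
#' @param seed integer seed.
#' @return list of simulation parameters.
#' @export
admixSimConfig <- function(n_sources = 4, n_markers = 2000,
                           fst_like_divergence = 0.2,
                           donor_blocks = list(), n_relatives = 3,
                           genotyping_error = 1e-3, recomb_rate = 1e-4,
                           n_per_source = 8, seed = 1) {
  stopifnot(n_sources >= 2, n_markers >= 10, fst_like_divergence >= 0,
            n_relatives >= 0, genotyping_error >= 0, genotyping_error < 0.5,
            recomb_rate >= 0, n_per_source >= 2)
  for (b in donor_blocks) {
    if (b$donor < 1 || b$donor >= n_sources)
      stop("donor index must name a non-background source (1..",
           n_sources - 1, ")")
    if (min(b$span) < 1 || max(b$span) > n_markers)
      stop("donor block span outside the marker range")
  }
  list(n_sources = n_sources, n_markers = n_markers,
       fst_like_divergence = fst_like_divergence,
       donor_blocks = donor_blocks, n_relatives = n_relatives,
       genotyping_error = genotyping_error, recomb_rate = recomb_rate,
       n_per_source = n_per_source, seed = seed)
}

#' Simulate source populations plus admixed test genomes
#'
#' Source allele frequencies drift independently from a common ancestral
#' frequency (Balding-Nichols beta model; at `fst_like_divergence >= 1`
#' each marker is a fixed difference diagnostic for one source). The test
#' genome and its relatives carry the background (last source) ancestry
#' except over the planted `donor_blocks`, where both haplotypes come from
#' the donor. Genotypes are binomial draws from the ancestry-specific
#' frequencies, with per-allele genotyping error.
#'
#' @param cfg an [admixSimConfig()] list.
#' @return list: `gm` ([GenotypeMatrix-class] with source, test and
#'   relative samples), `populations` (named vector for the source
#'   samples), `test_samples`, `source_freqs_true`, `pos_morgans`,
#'   `truth` (per-marker ancestry state labels and planted runs).
#' @export
simulateAdmixturePanel <- function(cfg = admixSimConfig()) {
  set.seed(cfg$seed)
  K <- cfg$n_sources; M <- cfg$n_markers
  src_names <- c(sprintf("S%d", seq_len(K - 1)), "BG")
  FF <- cfg$fst_like_divergence
  p0 <- stats::runif(M, 0.05, 0.95)
  f <- matrix(0, M, K, dimnames = list(NULL, src_names))
  if (FF >= 1) {
    carrier <- sample.int(K, M, replace = TRUE)
    f[] <- 0
    f[cbind(seq_len(M), carrier)] <- 1
  } else if (FF == 0) {
    f[] <- p0
  } else {
    shape <- (1 - FF) / FF
    for (s in seq_len(K)) f[, s] <- stats::rbeta(M, p0 * shape,
                                                 (1 - p0) * shape)
  }
  # ancestry truth for test + relatives (shared planted blocks)
  anc_a <- rep(K, M); anc_b <- rep(K, M)
  for (b in cfg$donor_blocks) {
    anc_a[b$span] <- b$donor
    anc_b[b$span] <- b$donor
  }
  truth_state <- paste(src_names[pmin(anc_a, anc_b)],
                       src_names[pmax(anc_a, anc_b)], sep = "/")
  e <- cfg$genotyping_error
  flip <- function(alleles) {
    err <- stats::runif(length(alleles)) < e
    ifelse(err, 1 - alleles, alleles)
  }
  draw_sample <- function(fa, fb) {
    a1 <- stats::rbinom(M, 1, fa)
    a2 <- stats::rbinom(M, 1, fb)
    as.integer(flip(a1) + flip(a2))
  }
  samples <- character(); calls <- list(); pops <- character()
  for (s in seq_len(K)) {
    for (i in seq_len(cfg$n_per_source)) {
      nm <- sprintf("%s_%d", src_names[s], i)
      samples <- c(samples, nm)
      calls[[nm]] <- draw_sample(f[, s], f[, s])
      pops[nm] <- src_names[s]
    }
  }
  fa <- f[cbind(seq_len(M), anc_a)]; fb <- f[cbind(seq_len(M), anc_b)]
  test_samples <- c("test1", if (cfg$n_relatives > 0)
    sprintf("rel%d", seq_len(cfg$n_relatives)))
  for (nm in test_samples) {
    samples <- c(samples, nm)
    calls[[nm]] <- draw_sample(fa, fb)
  }
  callm <- do.call(rbind, calls)
  sites <- data.frame(chrom = "chr1", pos = seq_len(M) * 10000L,
                      ref = "A", alt = "T", multiallelic = FALSE,
                      stringsAsFactors = FALSE)
  gm <- GenotypeMatrix(samples, sites, callm)
  runs <- if (length(cfg$donor_blocks)) do.call(rbind, lapply(
    cfg$donor_blocks, function(b)
      data.frame(donor = src_names[b$donor], start = min(b$span),
                 end = max(b$span), n_markers = length(b$span),
                 stringsAsFactors = FALSE)))
  else data.frame(donor = character(), start = integer(), end = integer(),
                  n_markers = integer())
  list(gm = gm, populations = pops, test_samples = test_samples,
       source_freqs_true = f,
       pos_morgans = (seq_len(M) - 1) * cfg$recomb_rate,
       truth = list(ancestry = truth_state, runs = runs,
                    background = "BG", config = cfg))
}

#' F1 pseudo-testcross simulation configuration
#'
#' @param n_progeny progeny count (the study design used 143).
#' @param n_markers informative markers, allocated to chromosomes in
#'   proportion to map length.
#' @param chrom_lengths_cM genetic length of each chromosome.
#' @param qtl list `chrom` (index), `pos_cM`, `effect` (fraction of
#'   phenotypic variance explained).
#' @param phenotype_noise environmental variance.
#' @param seed integer seed.
#' @return list of simulation parameters.
#' @export
crossSimConfig <- function(n_progeny = 143, n_markers = 300,
                           chrom_lengths_cM = c(80, 80, 80),
                           qtl = list(chrom = 1, pos_cM = 40, effect = 0.5),
                           phenotype_noise = 1, seed = 1) {
  stopifnot(n_progeny >= 2, n_markers >= 2 * length(chrom_lengths_cM),
            all(chrom_lengths_cM > 0), phenotype_noise > 0)
  if (qtl$chrom < 1 || qtl$chrom > length(chrom_lengths_cM))
    stop("qtl chromosome outside the genome")
  if (qtl$pos_cM < 0 || qtl$pos_cM > chrom_lengths_cM[qtl$chrom])
    stop("qtl position outside its chromosome")
  stopifnot(qtl$effect >= 0, qtl$effect < 1)
  list(n_progeny = n_progeny, n_markers = n_markers,
       chrom_lengths_cM = chrom_lengths_cM, qtl = qtl,
       phenotype_noise = phenotype_noise, seed = seed)
}

#' Simulate an F1 pseudo-testcross with a planted QTL
#'
#' One outbred focal parent (two phased haplotypes, "Mahan" and "Major")
#' crossed to a homozygous parent. Progeny inherit crossover mosaics of the
#' focal haplotypes (crossovers Poisson with mean length/100 per
#' chromosome, no interference); each marker's alternate allele sits on
#' one haplotype (the phase truth). The phenotype is
#' beta x \[inherited Mahan haplotype at the QTL\] + Gaussian noise, with
#' beta chosen so the QTL explains `qtl$effect` of the variance.
#'
#' @param cfg a [crossSimConfig()] list.
#' @return list: `x` (progeny x marker alternate-allele inheritance 0/1),
#'   `geno` (reference-allele counts 1/2), `markers` (marker, chrom,
#'   pos_bp, cM_true), `phenotype`, `parental_origin` (marker -> origin of
#'   its alternate allele), `truth` (haplotype mosaics, crossover counts,
#'   QTL genotype and effect).
#' @export
simulateF1Cross <- function(cfg = crossSimConfig()) {
  set.seed(cfg$seed)
  n_chr <- length(cfg$chrom_lengths_cM)
  alloc <- round(cfg$n_markers * cfg$chrom_lengths_cM /
                   sum(cfg$chrom_lengths_cM))
  alloc <- pmax(alloc, 2)
  mk <- do.call(rbind, lapply(seq_len(n_chr), function(c) {
    cm <- sort(stats::runif(alloc[c], 0, cfg$chrom_lengths_cM[c]))
    data.frame(marker = sprintf("c%d_m%03d", c, seq_along(cm)),
               chrom = sprintf("chr%d", c),
               pos_bp = round(cm * 250000) + 1L, cM_true = cm,
               stringsAsFactors = FALSE)
  }))
  rownames(mk) <- NULL
  m_tot <- nrow(mk)
  phase <- sample(1:2, m_tot, replace = TRUE)   # haplotype carrying the alt
  origin <- stats::setNames(c("Mahan", "Major")[phase], mk$marker)
  n <- cfg$n_progeny
  hap <- matrix(0L, n, m_tot)
  qtl_hap <- integer(n)
  cx_counts <- matrix(0L, n, n_chr)
  for (c in seq_len(n_chr)) {
    jj <- which(mk$chrom == sprintf("chr%d", c))
    len <- cfg$chrom_lengths_cM[c]
    for (i in seq_len(n)) {
      start <- sample(1:2, 1)
      ncx <- stats::rpois(1, len / 100)
      cx <- sort(stats::runif(ncx, 0, len))
      cx_counts[i, c] <- ncx
      hap_at <- function(pos) {
        h <- start + sum(cx < pos)
        if (h %% 2 == 1) 1L else 2L
      }
      start_parity <- start
      nswitch <- findInterval(mk$cM_true[jj], cx)
      hap[i, jj] <- ifelse((start_parity + nswitch) %% 2 == 1, 1L, 2L)
      if (c == cfg$qtl$chrom) qtl_hap[i] <- hap_at(cfg$qtl$pos_cM)
    }
  }
  x <- matrix(0L, n, m_tot,
              dimnames = list(sprintf("p%03d", seq_len(n)), mk$marker))
  for (j in seq_len(m_tot)) x[, j] <- as.integer(hap[, j] == phase[j])
  geno <- 2L - x
  z <- as.numeric(qtl_hap == 1L)
  r2 <- cfg$qtl$effect
  beta <- if (r2 > 0)
    sqrt(r2 * cfg$phenotype_noise / (0.25 * (1 - r2))) else 0
  phenotype <- beta * z + stats::rnorm(n, 0, sqrt(cfg$phenotype_noise))
  names(phenotype) <- rownames(x)
  list(x = x, geno = geno,
       markers = mk, phenotype = phenotype, parental_origin = origin,
       truth = list(haplotypes = hap, crossovers = cx_counts,
                    qtl_genotype = z, beta = beta,
                    phase = phase, qtl = cfg$qtl, config = cfg))
}

#' Read/write 12-column blast-like tabular hits
#'
#' The tabular dialect carries query and target ids in columns 1-2 and the
#' bitscore in column 12; genome labels are supplied by the caller since
#' the format does not carry them.
#'
#' @param path file path.
#' @param query_genome,target_genome genome labels for all rows.
#' @return `readBlastTab`: a hit data.frame; `writeBlastTab`: `path`,
#'   invisibly.
#' @export
readBlastTab <- function(path, query_genome, target_genome) {
  tb <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(tb) < 12) stop("expected 12-column blast tabular format")
  data.frame(query_gene = as.character(tb[[1]]),
             target_gene = as.character(tb[[2]]),
             query_genome = query_genome, target_genome = target_genome,
             bitscore = as.numeric(tb[[12]]), stringsAsFactors = FALSE)
}

#' @rdname readBlastTab
#' @param hits hit data.frame (one genome pair).
#' @export
writeBlastTab <- function(hits, path) {
  tb <- data.frame(hits$query_gene, hits$target_gene, 100, 0, 0, 0,
                   0, 0, 0, 0, 0, hits$bitscore)
  utils::write.table(tb, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a pan-genome table as TSV
#'
#' One row per entry: `pan_id`, `pan_chrom`, `pan_position`, then one
#' representative column and one comma-separated member column per genome.
#'
#' @param pg a [Pangenome-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePangenomeTsv <- function(pg, path) {
  ent <- pg@entries
  for (g in pg@genomes) {
    ent[[paste0("rep_", g)]] <- pg@representative[, g]
    ent[[paste0("members_", g)]] <- vapply(pg@members[[g]], paste,
                                           character(1), collapse = ",")
  }
  utils::write.table(ent, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
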
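#' Compute collinear blocks for every ordered genome pair
#'
#' Hits are pruned to `n_top` per (query gene, target genome) (pan-genome
#' runs use 1 hit/gene/genome), converted to gene-rank anchors per
#' (query chromosome, target chromosome) pair, and chained with
#' [chainCollinearBlocks()]. Within-genome pairs are skipped (homeolog
#' blocks are handled by [countHomeologBlocks()]).
#'
#' @param genes combined gene-model table (all genomes, with `rank`).
#' @param hits similarity hit table across genomes.
#' @param params [panChainParams()] list.
#' @param n_top hits per gene per target genome before chaining.
#' @return data.frame of blocks with `qgenome`, `tgenome`, `qchrom`,
#'   `tchrom`, `orientation`, `n_anchors`, rank spans, and a list column
#'   `anchors` (data.frame `q`, `t` sorted by `q`).
#' @export
syntenicBlocks <- function(genes, hits, params = panChainParams(), n_top = 1) {
  pruned <- pruneHits(hits, n_top = n_top)
  pruned <- pruned[pruned$query_genome != pruned$target_genome, , drop = FALSE]
  gk <- gene_key(genes$genome, genes$gene_id)
  qi <- match(gene_key(pruned$query_genome, pruned$query_gene), gk)
  ti <- match(gene_key(pruned$target_genome, pruned$target_gene), gk)
  pruned <- pruned[!is.na(qi) & !is.na(ti), , drop = FALSE]
  qi <- qi[!is.na(qi)]; ti <- ti[!is.na(ti)]
  df <- data.frame(qgenome = pruned$query_genome, tgenome = pruned$target_genome,
                   qchrom = genes$chrom[qi], tchrom = genes$chrom[ti],
                   q = genes$rank[qi], t = genes$rank[ti],
                   stringsAsFactors = FALSE)
  df <- unique(df)
  if (nrow(df) == 0) return(emptyPairBlocks())
  grp <- paste(df$qgenome, df$tgenome, df$qchrom, df$tchrom, sep = "\r")
  out <- lapply(split(seq_len(nrow(df)), grp), function(idx) {
    sub <- df[idx, , drop = FALSE]
    b <- chainCollinearBlocks(sub[, c("q", "t")], params)
    if (nrow(b) == 0) return(NULL)
    b$qgenome <- sub$qgenome[1]; b$tgenome <- sub$tgenome[1]
    b$qchrom <- sub$qchrom[1]; b$tchrom <- sub$tchrom[1]
    b$anchors <- lapply(b$anchor_idx, function(ai) {
      a <- sub[ai, c("q", "t")]
      a[order(a$q), , drop = FALSE]
    })
    b$anchor_idx <- NULL
    b
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) return(emptyPairBlocks())
  rownames(out) <- NULL
  out
}

emptyPairBlocks <- function() {
  out <- data.frame(block_id = integer(), orientation = character(),
                    n_anchors = integer(), q_start = numeric(),
                    q_end = numeric(), t_start = numeric(), t_end = numeric(),
                    qgenome = character(), tgenome = character(),
                    qchrom = character(), tchrom = character(),
                    stringsAsFactors = FALSE)
  out$anchors <- list()
  out
}

#' Constrain a hit network to synteny
#'
#' Cross-genome hits are retained only when their (query rank, target rank)
#' anchor falls inside the bounding box of a collinear block for that
#' genome/chromosome pair; isolated (e.g. small translocated) hits are
#' removed. Within-genome hits across different chromosomes (homeologous
#' regions) are masked from orthologous pairing; within-genome same-
#' chromosome hits are kept only within `params$max_gap` ranks (tandem
#' proximity).
#'
#' @param hits hit table (any pruning level).
#' @param blocks output of [syntenicBlocks()].
#' @param genes combined gene-model table.
#' @param params [panChainParams()] list.
#' @return the synteny-constrained hit table.
#' @export
constrainToSynteny <- function(hits, blocks, genes, params = panChainParams()) {
  gk <- gene_key(genes$genome, genes$gene_id)
  qi <- match(gene_key(hits$query_genome, hits$query_gene), gk)
  ti <- match(gene_key(hits$target_genome, hits$target_gene), gk)
  ok <- !is.na(qi) & !is.na(ti)
  hits <- hits[ok, , drop = FALSE]; qi <- qi[ok]; ti <- ti[ok]
  qc <- genes$chrom[qi]; tc <- genes$chrom[ti]
  qr <- genes$rank[qi]; tr <- genes$rank[ti]
  within <- hits$query_genome == hits$target_genome
  keep_within <- within & qc == tc & abs(qr - tr) <= params$max_gap &
    hits$query_gene != hits$target_gene
  keep_cross <- rep(FALSE, nrow(hits))
  cross <- which(!within)
  if (length(cross) && nrow(blocks)) {
    bkey <- paste(blocks$qgenome, blocks$tgenome, blocks$qchrom, blocks$tchrom,
                  sep = "\r")
    hkey <- paste(hits$query_genome, hits$target_genome, qc, tc, sep = "\r")
    for (i in cross) {
      rows <- which(bkey == hkey[i])
      if (!length(rows)) next
      inside <- qr[i] >= blocks$q_start[rows] & qr[i] <= blocks$q_end[rows] &
        tr[i] >= blocks$t_start[rows] & tr[i] <= blocks$t_end[rows]
      keep_cross[i] <- any(inside)
    }
  }
  out <- hits[keep_within | keep_cross, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# summed within-genome bitscore per gene (used for representative choice)
within_genome_bitscore <- function(hits) {
  w <- hits[hits$query_genome == hits$target_genome &
              hits$query_gene != hits$target_gene, , drop = FALSE]
  if (nrow(w) == 0) return(stats::setNames(numeric(), character()))
  tapply(w$bitscore, gene_key(w$query_genome, w$query_gene), sum)
}

#' Condense tandem arrays within orthogroups
#'
#' Within one genome and orthogroup, genes on the same chromosome whose
#' ranks lie within `max_gap` of the next array member collapse into a
#' single tandem array with one representative: the gene with the highest
#' summed within-genome blast bitscore, ties broken by physical centrality
#' (closest to the median rank of the orthogroup members on that
#' chromosome) and then by gene length (longer wins), then gene id.
#'
#' @param og orthogroup table ([clusterOrthogroups()] output).
#' @param genes combined gene-model table.
#' @param hits hit table (for within-genome bitscore sums).
#' @param max_gap rank distance linking members of one array.
#' @return data.frame `og_id`, `genome`, `gene_id`, `chrom`, `rank`,
#'   `array_id`, `is_representative`.
#' @export
condenseTandemArrays <- function(og, genes, hits, max_gap = 20) {
  gk <- gene_key(genes$genome, genes$gene_id)
  gi <- match(gene_key(og$genome, og$gene_id), gk)
  if (anyNA(gi)) stop("orthogroup table references unknown genes")
  df <- data.frame(og_id = og$og_id, genome = og$genome, gene_id = og$gene_id,
                   chrom = genes$chrom[gi], rank = genes$rank[gi],
                   length = genes$length[gi], stringsAsFactors = FALSE)
  bs <- within_genome_bitscore(hits)
  df$sum_bitscore <- unname(bs[gene_key(df$genome, df$gene_id)])
  df$sum_bitscore[is.na(df$sum_bitscore)] <- 0
  grp <- paste(df$og_id, df$genome, df$chrom, sep = "\r")
  df <- df[order(grp, df$rank), , drop = FALSE]
  grp <- paste(df$og_id, df$genome, df$chrom, sep = "\r")
  new_grp <- c(TRUE, grp[-1] != grp[-length(grp)])
  gap_break <- c(TRUE, diff(df$rank) > max_gap)
  df$array_id <- cumsum(new_grp | gap_break)
  med_rank <- stats::ave(df$rank, paste(df$og_id, df$genome, df$chrom, sep = "\r"),
                         FUN = stats::median)
  df$centrality <- abs(df$rank - med_rank)
  rep_flag <- logical(nrow(df))
  for (idx in split(seq_len(nrow(df)), df$array_id)) {
    sub <- df[idx, , drop = FALSE]
    o <- order(-sub$sum_bitscore, sub$centrality, -sub$length, sub$gene_id)
    rep_flag[idx[o[1]]] <- TRUE
  }
  df$is_representative <- rep_flag
  df$centrality <- NULL
  rownames(df) <- NULL
  df
}

# interpolate one gene's rank into reference rank space through the
# enclosing collinear block (linear between the two nearest anchors)
interpolate_rank <- function(blocks, genome, chrom, rank, reference) {
  rows <- which(blocks$qgenome == genome & blocks$tgenome == reference &
                  blocks$qchrom == chrom &
                  blocks$q_start <= rank & blocks$q_end >= rank)
  if (!length(rows)) return(NULL)
  row <- rows[order(-blocks$n_anchors[rows])][1]
  a <- blocks$anchors[[row]]
  if (rank <= a$q[1]) return(list(chrom = blocks$tchrom[row], pos = a$t[1]))
  n <- nrow(a)
  if (rank >= a$q[n]) return(list(chrom = blocks$tchrom[row], pos = a$t[n]))
  hi <- which(a$q >= rank)[1]
  lo <- hi - 1L
  if (a$q[hi] == rank) return(list(chrom = blocks$tchrom[row], pos = a$t[hi]))
  frac <- (rank - a$q[lo]) / (a$q[hi] - a$q[lo])
  list(chrom = blocks$tchrom[row], pos = a$t[lo] + frac * (a$t[hi] - a$t[lo]))
}

#' Place orthogroups on the reference gene order
#'
#' Builds the ordered pan-genome. Orthogroups single-copy in the reference
#' take the rank-order location of that gene; multi-copy orthogroups take
#' the location of the member with the highest summed within-genome blast
#' bitscore (ties by centrality then gene length); reference-absent
#' orthogroups take the mean syntenic position of each other genome's
#' representative member, interpolated into reference rank space through
#' its enclosing collinear block. Orthogroups with no placeable member go
#' to the `"unplaced"` pseudo-chromosome. Entries are sorted by
#' (`pan_chrom`, `pan_position`, `pan_id`).
#'
#' @param og orthogroup table.
#' @param genes combined gene-model table.
#' @param hits hit table.
#' @param blocks [syntenicBlocks()] output (for interpolation).
#' @param reference reference genome label.
#' @param outgroup optional outgroup genome excluded from PAV summaries.
#' @param params [panChainParams()] list (tandem gap reuses `max_gap`).
#' @return A [Pangenome-class] object.
#' @export
placeOrthogroups <- function(og, genes, hits, blocks, reference,
                             outgroup = NA_character_,
                             params = panChainParams()) {
  genomes <- sort(unique(genes$genome))
  if (!reference %in% genomes) stop("reference genome not in gene table")
  cond <- condenseTandemArrays(og, genes, hits, max_gap = params$max_gap)
  og_ids <- sort(unique(cond$og_id))
  n <- length(og_ids)
  presence <- matrix(FALSE, n, length(genomes),
                     dimnames = list(og_ids, genomes))
  representative <- matrix(NA_character_, n, length(genomes),
                           dimnames = list(og_ids, genomes))
  members <- lapply(genomes, function(g) rep(list(character()), n))
  names(members) <- genomes
  pan_chrom <- rep("unplaced", n)
  pan_pos <- rep(NA_real_, n)
  by_og <- split(seq_len(nrow(cond)), cond$og_id)
  for (k in seq_len(n)) {
    idx <- by_og[[og_ids[k]]]
    sub <- cond[idx, , drop = FALSE]
    for (g in unique(sub$genome)) {
      gs <- sub[sub$genome == g, , drop = FALSE]
      presence[k, g] <- TRUE
      members[[g]][[k]] <- gs$gene_id
      reps <- gs[gs$is_representative, , drop = FALSE]
      o <- order(-reps$sum_bitscore,
                 abs(reps$rank - stats::median(gs$rank)), -reps$length,
                 reps$gene_id)
      representative[k, g] <- reps$gene_id[o[1]]
    }
    ref_units <- sub[sub$genome == reference & sub$is_representative, , drop = FALSE]
    if (nrow(ref_units) >= 1) {
      if (nrow(ref_units) == 1) {
        pick <- ref_units
      } else {
        o <- order(-ref_units$sum_bitscore,
                   abs(ref_units$rank - stats::median(sub$rank[sub$genome == reference])),
                   -ref_units$length, ref_units$gene_id)
        pick <- ref_units[o[1], , drop = FALSE]
      }
      pan_chrom[k] <- pick$chrom[1]
      pan_pos[k] <- pick$rank[1]
    } else {
      proj <- list()
      for (g in setdiff(unique(sub$genome), c(reference, outgroup))) {
        rg <- representative[k, g]
        gi <- which(sub$genome == g & sub$gene_id == rg)
        p <- interpolate_rank(blocks, g, sub$chrom[gi], sub$rank[gi], reference)
        if (!is.null(p)) proj[[length(proj) + 1L]] <- p
      }
      if (length(proj)) {
        chroms <- vapply(proj, `[[`, character(1), "chrom")
        tab <- sort(table(chroms), decreasing = TRUE)
        best <- names(tab)[tab == max(tab)]
        chrom <- sort(best)[1]
        pos <- vapply(proj[chroms == chrom], `[[`, numeric(1), "pos")
        pan_chrom[k] <- chrom
        pan_pos[k] <- mean(pos)
      }
    }
  }
  entries <- data.frame(pan_id = og_ids, pan_chrom = pan_chrom,
                        pan_position = pan_pos, stringsAsFactors = FALSE)
  unpl <- entries$pan_chrom == "unplaced"
  ord <- order(unpl, entries$pan_chrom, entries$pan_position, entries$pan_id)
  entries <- entries[ord, , drop = FALSE]
  rownames(entries) <- NULL
  presence <- presence[ord, , drop = FALSE]
  representative <- representative[ord, , drop = FALSE]
  members <- lapply(members, function(m) m[ord])
  new("Pangenome", entries = entries, genomes = genomes, presence = presence,
      members = members, representative = representative,
      reference = reference, outgroup = as.character(outgroup))
}

#' Full synteny-constrained pan-genome pipeline
#'
#' Convenience wrapper: prune hits (1 per gene per genome), chain collinear
#' blocks, constrain the hit network to synteny, re-cluster orthogroups on
#' the surviving network, and place them on the reference gene order.
#'
#' @inheritParams placeOrthogroups
#' @param n_top hits per gene per genome for the syntenic chaining step.
#' @return A [Pangenome-class] object.
#' @export
buildPangenome <- function(genes, hits, reference, outgroup = NA_character_,
                           params = panChainParams(), n_top = 1) {
  blocks <- syntenicBlocks(genes, hits, params, n_top = n_top)
  constrained <- constrainToSynteny(hits, blocks, genes, params)
  og <- clusterOrthogroups(constrained, genes)
  placeOrthogroups(og, genes, hits, blocks, reference, outgroup, params)
}

#' Presence-absence table and summary
#'
#' Derives per-orthogroup PAV flags from a pan-genome: `complete` (present
#' in every non-outgroup genome), `incomplete` (absent somewhere) and
#' `private` (present in exactly one genome). The outgroup, when set, is
#' excluded from the accounting.
#'
#' @param pg a [Pangenome-class].
#' @return list with `matrix` (logical entries x genomes), `flags`
#'   (data.frame `pan_id`, `complete`, `incomplete`, `private_to`), and
#'   `summary` (counts and fractions).
#' @export
pavTable <- function(pg) {
  genomes <- setdiff(pg@genomes, pg@outgroup)
  m <- pg@presence[, genomes, drop = FALSE]
  n_pres <- rowSums(m)
  complete <- n_pres == length(genomes)
  private_to <- rep(NA_character_, nrow(m))
  one <- n_pres == 1
  if (any(one))
    private_to[one] <- genomes[apply(m[one, , drop = FALSE], 1, which)]
  flags <- data.frame(pan_id = pg@entries$pan_id, complete = complete,
                      incomplete = !complete, private_to = private_to,
                      stringsAsFactors = FALSE)
  priv_counts <- table(factor(private_to, levels = genomes))
  summary <- list(
    n_orthogroups = nrow(m),
    n_complete = sum(complete),
    n_incomplete = sum(!complete),
    incomplete_fraction = mean(!complete),
    private_per_genome = as.integer(priv_counts)
  )
  names(summary$private_per_genome) <- genomes
  list(matrix = m, flags = flags, summary = summary)
}

#' Runs of consecutive absences in one genome
#'
#' Maximal runs of `min_run` or more consecutive pan-genome entries (by pan
#' order within a pan chromosome) that are absent in the focal genome.
#'
#' @param pg a [Pangenome-class].
#' @param focal_genome the genome scored for absences.
#' @param min_run minimum run length (default 5 consecutive genes).
#' @return data.frame `pan_chrom`, `start_pan_id`, `end_pan_id`,
#'   `start_index`, `end_index`, `run_length`.
#' @export
absenceRuns <- function(pg, focal_genome, min_run = 5) {
  stopifnot(focal_genome %in% pg@genomes)
  ent <- pg@entries
  absent <- !pg@presence[, focal_genome]
  out <- list()
  for (ch in unique(ent$pan_chrom)) {
    if (ch == "unplaced") next
    idx <- which(ent$pan_chrom == ch)
    r <- rle(absent[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values & r$lengths >= min_run)
    for (k in keep) {
      i0 <- idx[starts[k]]; i1 <- idx[ends[k]]
      out[[length(out) + 1L]] <- data.frame(
        pan_chrom = ch, start_pan_id = ent$pan_id[i0],
        end_pan_id = ent$pan_id[i1], start_index = i0, end_index = i1,
        run_length = r$lengths[k], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(pan_chrom = character(), start_pan_id = character(),
                      end_pan_id = character(), start_index = integer(),
                      end_index = integer(), run_length = integer()))
  do.call(rbind, out)
}

#' Classify the sequence underlying an annotation absence
#'
#' Aligns a CDS (best local alignment) against the syntenic genomic region
#' where the absent gene should reside. Coverage is 100 x matches / CDS
#' length; identity is computed over aligned columns as
#' matches / (matches + mismatches). Categories: `very_similar` requires
#' coverage > 99 and identity >= 95; `diverged` requires coverage >= 75 and
#' identity >= 75 (and not very_similar); anything else is `absent`.
#'
#' @param cds CDS sequence (character or `DNAString`).
#' @param syntenic_region genomic region sequence located via flanking
#'   pan-genome anchors.
#' @return list `coverage_pct`, `identity_pct`, `category`.
#' @export
classifyAbsence <- function(cds, syntenic_region) {
  cds <- as.character(cds); syntenic_region <- as.character(syntenic_region)
  if (!nzchar(cds)) stop("empty CDS")
  if (!nzchar(syntenic_region)) stop("empty syntenic region")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(cds), Biostrings::DNAString(syntenic_region),
    type = "local", substitutionMatrix = mat,
    gapOpening = 4, gapExtension = 1)
  matches <- Biostrings::nmatch(aln)
  mismatches <- Biostrings::nmismatch(aln)
  coverage <- 100 * matches / nchar(cds)
  identity <- if (matches + mismatches == 0) 0 else
    100 * matches / (matches + mismatches)
  category <- if (coverage > 99 && identity >= 95) "very_similar"
  else if (coverage >= 75 && identity >= 75) "diverged"
  else "absent"
  list(coverage_pct = coverage, identity_pct = identity, category = category)
}

#' Two-sided hypergeometric (Fisher) p-value by tail summation
#'
#' Exact two-sided p-value for a 2x2 table: the sum of probabilities of all
#' hypergeometric outcomes no more likely than the observed one.
#'
#' @param a,b,c,d the 2x2 cell counts (a = focal-in-interval).
#' @return p-value in (0, 1].
#' @export
hypergeomTwoSided <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  m <- a + c          # total focal (white balls)
  nn <- b + d         # total non-focal
  k <- a + b          # interval size (draws)
  lo <- max(0, k - nn); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, nn, k)
  obs <- stats::dhyper(a, m, nn, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

#' Private-gene enrichment in a pan-genome interval
#'
#' Tests whether entries private to a focal genome are over-represented in
#' an interval of the pan-genome (e.g. an introgression block), via the
#' exact two-sided hypergeometric test on the (interval vs rest) x
#' (private-to-focal vs not) table. Also reports the sample odds ratio and
#' the private fraction (e.g. 8 private among 46 interval orthogroups =
#' 17.4%).
#'
#' @param pav [pavTable()] output.
#' @param interval_ids pan ids of the entries inside the interval.
#' @param focal_genome genome whose private entries are scored.
#' @return list `private_fraction_pct` (one decimal), `odds_ratio`,
#'   `p_value`, and the 2x2 `table`.
#' @export
intervalPrivateEnrichment <- function(pav, interval_ids, focal_genome) {
  flags <- pav$flags
  if (!length(interval_ids)) stop("interval is empty")
  inside <- flags$pan_id %in% interval_ids
  if (!any(inside)) stop("interval is disjoint from the pan-genome")
  priv <- !is.na(flags$private_to) & flags$private_to == focal_genome
  a <- sum(inside & priv); b <- sum(inside & !priv)
  c <- sum(!inside & priv); d <- sum(!inside & !priv)
  or <- if (b == 0 || c == 0) {
    if (a == 0) 0 else Inf
  } else (a * d) / (b * c)
  if (a == 0) or <- 0
  list(private_fraction_pct = round(100 * a / (a + b), 1),
       odds_ratio = or,
       p_value = hypergeomTwoSided(a, b, c, d),
       table = matrix(c(a, b, c, d), 2, 2, byrow = TRUE,
                      dimnames = list(c("interval", "rest"),
                                      c("private", "other"))))
}

#' Percent identity of two proteins (internal-gap-penalised)
#'
#' Global alignment identity computed as 100 x identical positions /
#' (aligned positions + internal gap positions), with terminal gaps
#' excluded. E.g. ACDEFG vs ACDFG aligns with one internal gap: 5 identical
#' over (5 aligned + 1 gap) = 83.3%.
#'
#' @param a,b protein sequences (character or `AAString`).
#' @return identity percentage.
#' @export
proteinIdentityPct <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(as.character(a)), Biostrings::AAString(as.character(b)),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  non_gap <- which(pa != "-" & pb != "-")
  if (!length(non_gap)) return(0)
  lo <- min(non_gap); hi <- max(non_gap)
  pa <- pa[lo:hi]; pb <- pb[lo:hi]
  identical_n <- sum(pa == pb & pa != "-")
  aligned_n <- sum(pa != "-" & pb != "-")
  gap_n <- sum(xor(pa == "-", pb == "-"))
  100 * identical_n / (aligned_n + gap_n)
}

#' Project the pan-genome onto an alternative haplotype assembly
#'
#' Pairs each pan-genome entry's representative in the focal genome with
#' its reciprocal-best ortholog in the alternative haplotype annotation,
#' places every alternative contig at the midpoint of its members' primary
#' syntenic (gene-rank) positions, and classifies each entry:
#' `both` (ortholog on both haplotypes, with percent identity),
#' `primary_only_with_alt_contig` (no alt ortholog but an alt contig spans
#' the locus: higher-confidence PAV), `primary_only_no_alt_contig` (likely
#' a homozygous, collapsed region), while alternative-only genes are
#' reported separately as the `alt_only` class.
#'
#' @param pg a [Pangenome-class].
#' @param alt_genes gene-model table of the alternative haplotype
#'   annotation (its `chrom` values are contig names).
#' @param hits_pa hit table between the primary genome and the alternative
#'   haplotype (both directions).
#' @param primary_prot,alt_prot named `AAStringSet`s of protein sequences
#'   (names = gene ids); used for percent identity of `both` pairs. May be
#'   `NULL` to skip identity computation.
#' @param genome focal (primary) genome label.
#' @return list `comparisons` (per placed entry: class, alt gene, identity),
#'   `alt_only` (alt genes without a primary ortholog), `contigs`
#'   (midpoint syntenic location per alt contig).
#' @export
projectToAltHaplotype <- function(pg, alt_genes, hits_pa,
                                  primary_prot = NULL, alt_prot = NULL,
                                  genome) {
  stopifnot(genome %in% pg@genomes)
  alt_label <- unique(alt_genes$genome)
  stopifnot(length(alt_label) == 1)
  p2a <- hits_pa[hits_pa$query_genome == genome &
                   hits_pa$target_genome == alt_label, , drop = FALSE]
  a2p <- hits_pa[hits_pa$query_genome == alt_label &
                   hits_pa$target_genome == genome, , drop = FALSE]
  best_of <- function(h) {
    if (nrow(h) == 0) return(stats::setNames(character(), character()))
    h <- h[order(h$query_gene, -h$bitscore, h$target_gene), , drop = FALSE]
    h <- h[!duplicated(h$query_gene), , drop = FALSE]
    stats::setNames(h$target_gene, h$query_gene)
  }
  best_pa <- best_of(p2a)
  best_ap <- best_of(a2p)
  # reciprocal best pairs primary <-> alt
  rbh_p <- names(best_pa)[!is.na(best_ap[best_pa]) &
                            best_ap[best_pa] == names(best_pa)]
  pair_alt <- best_pa[rbh_p]
  # contig placement: midpoint of members' primary syntenic positions,
  # taken in the pan coordinate system (reference gene ranks)
  contigs <- data.frame(contig = character(), chrom = character(),
                        midpoint = numeric(), span_lo = numeric(),
                        span_hi = numeric(), stringsAsFactors = FALSE)
  ent <- pg@entries
  # rank of each entry's focal representative = pan position if reference;
  # use pan_position as the primary syntenic coordinate system
  rep_focal <- pg@representative[, genome]
  pos_of_gene <- stats::setNames(ent$pan_position, rep_focal)
  chrom_of_gene <- stats::setNames(ent$pan_chrom, rep_focal)
  alt_members <- best_ap[!is.na(best_ap)]
  am <- data.frame(alt_gene = names(alt_members), prim_gene = unname(alt_members),
                   stringsAsFactors = FALSE)
  am$contig <- alt_genes$chrom[match(am$alt_gene, alt_genes$gene_id)]
  am$pos <- pos_of_gene[am$prim_gene]
  am$chrom <- chrom_of_gene[am$prim_gene]
  am <- am[!is.na(am$pos) & !is.na(am$chrom) & am$chrom != "unplaced", , drop = FALSE]
  if (nrow(am)) {
    contigs <- do.call(rbind, lapply(split(am, am$contig), function(s) {
      tab <- sort(table(s$chrom), decreasing = TRUE)
      ch <- names(tab)[1]
      p <- s$pos[s$chrom == ch]
      data.frame(contig = s$contig[1], chrom = ch,
                 midpoint = (min(p) + max(p)) / 2,
                 span_lo = min(p), span_hi = max(p), stringsAsFactors = FALSE)
    }))
    rownames(contigs) <- NULL
  }
  # entry classification
  has_focal <- pg@presence[, genome]
  idx <- which(has_focal)
  cls <- character(length(idx)); altg <- rep(NA_character_, length(idx))
  ident <- rep(NA_real_, length(idx))
  for (j in seq_along(idx)) {
    i <- idx[j]
    rg <- rep_focal[i]
    if (!is.na(rg) && rg %in% rbh_p) {
      cls[j] <- "both"
      altg[j] <- unname(pair_alt[rg])
      if (!is.null(primary_prot) && !is.null(alt_prot) &&
          rg %in% names(primary_prot) && altg[j] %in% names(alt_prot)) {
        ident[j] <- proteinIdentityPct(primary_prot[[rg]], alt_prot[[altg[j]]])
      }
    } else {
      covered <- nrow(contigs) > 0 &&
        any(contigs$chrom == ent$pan_chrom[i] &
              contigs$span_lo <= ent$pan_position[i] &
              contigs$span_hi >= ent$pan_position[i])
      cls[j] <- if (isTRUE(covered)) "primary_only_with_alt_contig"
      else "primary_only_no_alt_contig"
    }
  }
  comparisons <- data.frame(pan_id = ent$pan_id[idx],
                            pan_chrom = ent$pan_chrom[idx],
                            pan_position = ent$pan_position[idx],
                            primary_gene = rep_focal[idx],
                            class = cls, alt_gene = altg,
                            identity_pct = ident, stringsAsFactors = FALSE)
  alt_only_genes <- setdiff(alt_genes$gene_id, unname(pair_alt))
  ao <- data.frame(alt_gene = alt_only_genes,
                   contig = alt_genes$chrom[match(alt_only_genes,
                                                  alt_genes$gene_id)],
                   stringsAsFactors = FALSE)
  ao$chrom <- contigs$chrom[match(ao$contig, contigs$contig)]
  ao$midpoint <- contigs$midpoint[match(ao$contig, contigs$contig)]
  ao$class <- "alt_only"
  list(comparisons = comparisons, alt_only = ao, contigs = contigs)
}
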
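#' Prune similarity hits to the top n per query gene and target genome
#'
#' For each (query gene, target genome) only the `n_top` highest-bitscore
#' hits are retained (default 2, so a WGD genome can contribute both the
#' ortholog and the homeolog). Ties at the cutoff are broken by keeping the
#' lexicographically smaller target gene id. Self hits of a gene to itself
#' are always removed.
#'
#' @param hits data.frame with columns `query_gene`, `target_gene`,
#'   `query_genome`, `target_genome`, `bitscore`.
#' @param n_top hits retained per (query gene, target genome).
#' @return the pruned hit data.frame, with attribute `n_top`.
#' @export
pruneHits <- function(hits, n_top = 2) {
  if (n_top < 1) stop("n_top must be >= 1")
  stopifnot(all(c("query_gene", "target_gene", "query_genome",
                  "target_genome", "bitscore") %in% names(hits)))
  if (any(!is.finite(hits$bitscore))) stop("bitscores must be finite")
  self <- hits$query_gene == hits$target_gene &
    hits$query_genome == hits$target_genome
  hits <- hits[!self, , drop = FALSE]
  if (nrow(hits) == 0) {
    attr(hits, "n_top") <- n_top
    return(hits)
  }
  key <- paste(hits$query_genome, hits$query_gene, hits$target_genome, sep = "\r")
  ord <- order(key, -hits$bitscore, hits$target_gene)
  hits <- hits[ord, , drop = FALSE]
  key <- key[ord]
  within_rank <- stats::ave(seq_along(key), key, FUN = seq_along)
  out <- hits[within_rank <= n_top, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_top") <- n_top
  out
}

gene_key <- function(genome, gene_id) paste(genome, gene_id, sep = "\r")

#' Cluster genes into orthogroups by reciprocal hit components
#'
#' Orthogroups are the connected components of the undirected graph on
#' genes with an edge for every retained reciprocal hit pair (a hit
#' retained in both query->target and target->query direction). Genes with
#' no retained reciprocal hit become singleton orthogroups. This is a
#' deterministic stand-in for MCL-based orthology clustering.
#'
#' @param hits pruned hit data.frame (see [pruneHits()]).
#' @param genes gene-model data.frame defining the gene universe
#'   (`genome`, `gene_id`); genes absent from `hits` become singletons.
#' @return data.frame with columns `og_id`, `genome`, `gene_id`; every gene
#'   appears exactly once.
#' @export
clusterOrthogroups <- function(hits, genes) {
  all_keys <- gene_key(genes$genome, genes$gene_id)
  if (anyDuplicated(all_keys)) stop("duplicate (genome, gene_id) in genes")
  if (nrow(hits)) {
    a <- gene_key(hits$query_genome, hits$query_gene)
    b <- gene_key(hits$target_genome, hits$target_gene)
    unknown <- setdiff(c(a, b), all_keys)
    if (length(unknown)) stop("hits reference unknown genes: ",
                              paste(utils::head(unknown, 3), collapse = ", "))
    fwd <- paste(a, b, sep = "\n")
    rev <- paste(b, a, sep = "\n")
    reciprocal <- fwd %in% rev
    ea <- a[reciprocal]; eb <- b[reciprocal]
  } else {
    ea <- eb <- character()
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = ea, to = eb, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = all_keys, stringsAsFactors = FALSE)
  )
  comp <- igraph::components(g)$membership
  comp <- comp[all_keys]
  # stable og ids independent of input order: number components by their
  # lexicographically smallest member key
  min_key <- tapply(all_keys, comp, min)
  renum <- stats::setNames(rank(min_key, ties.method = "first"),
                           names(min_key))
  og <- sprintf("OG%06d", renum[as.character(comp)])
  data.frame(og_id = og, genome = genes$genome, gene_id = genes$gene_id,
             stringsAsFactors = FALSE)
}

# Longest monotone chain under a gap constraint, one orientation.
# anchors: matrix with columns q, t (already unique). dir = +1 or -1.
# Returns integer indices of the chain (possibly length 0).
longest_chain_dir <- function(q, t, dir, max_gap) {
  n <- length(q)
  if (n == 0) return(integer())
  tt <- if (dir < 0) -t else t
  ord <- order(q, tt)
  q <- q[ord]; tt <- tt[ord]
  len <- rep(1L, n); pred <- rep(0L, n)
  for (i in seq_len(n)) {
    dq <- q[i] - q; dt <- tt[i] - tt
    ok <- which(dq >= 1 & dq <= max_gap & dt >= 0 & dt <= max_gap)
    ok <- ok[ok < i]
    if (length(ok)) {
      best <- max(len[ok])
      cand <- ok[len[ok] == best]
      # deterministic predecessor: smallest q, then smallest t
      j <- cand[order(q[cand], tt[cand])][1]
      len[i] <- len[j] + 1L
      pred[i] <- j
    }
  }
  best_len <- max(len)
  ends <- which(len == best_len)
  # among maximal chains prefer the one with the smallest starting q rank:
  starts <- vapply(ends, function(e) {
    while (pred[e] > 0L) e <- pred[e]
    q[e]
  }, numeric(1))
  e <- ends[order(starts, q[ends])][1]
  chain <- integer(best_len); k <- best_len
  while (e > 0L) { chain[k] <- e; k <- k - 1L; e <- pred[e] }
  ord[chain]
}

#' Chain anchors into collinear blocks
#'
#' Greedy extraction of maximal monotone chains from a set of anchor
#' positions in (query rank, target rank) space. A chain is strictly
#' increasing in query rank, monotone (increasing = "same" orientation, or
#' decreasing = "inverted") in target rank, and consecutive anchors may
#' differ by at most `max_gap` ranks on both axes. The longest chain is
#' extracted first (ties broken by smaller starting query rank, same
#' orientation preferred), its anchors are removed, and the process repeats
#' until no chain reaches `min_size` anchors.
#'
#' @param anchors data.frame or matrix with columns `q`, `t` (gene ranks);
#'   rows must be unique.
#' @param params a [chainParams()] list (`max_gap`, `min_size` used).
#' @return data.frame of blocks: `block_id`, `orientation`, `n_anchors`,
#'   `q_start`, `q_end`, `t_start`, `t_end`, plus a list column `anchor_idx`
#'   of row indices into `anchors`.
#' @export
chainCollinearBlocks <- function(anchors, params = chainParams()) {
  anchors <- as.data.frame(anchors)
  if (nrow(anchors) == 0) return(emptyBlocks())
  names(anchors)[1:2] <- c("q", "t")
  if (anyDuplicated(anchors[, c("q", "t")])) stop("anchors must be deduplicated")
  avail <- seq_len(nrow(anchors))
  blocks <- list()
  repeat {
    if (length(avail) == 0) break
    q <- anchors$q[avail]; t <- anchors$t[avail]
    c_same <- longest_chain_dir(q, t, +1, params$max_gap)
    c_inv <- longest_chain_dir(q, t, -1, params$max_gap)
    pick_same <- length(c_same) >= length(c_inv)
    if (length(c_same) == length(c_inv) && length(c_same) > 0) {
      # tie between orientations: smaller starting query rank wins
      pick_same <- q[c_same[1]] <= q[c_inv[1]]
    }
    chain <- if (pick_same) c_same else c_inv
    if (length(chain) < params$min_size) break
    idx <- avail[chain]
    blocks[[length(blocks) + 1L]] <- list(
      orientation = if (pick_same) "same" else "inverted",
      anchor_idx = idx
    )
    avail <- setdiff(avail, idx)
  }
  if (!length(blocks)) return(emptyBlocks())
  out <- do.call(rbind, lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    qs <- anchors$q[b$anchor_idx]; ts <- anchors$t[b$anchor_idx]
    data.frame(block_id = i, orientation = b$orientation,
               n_anchors = length(b$anchor_idx),
               q_start = min(qs), q_end = max(qs),
               t_start = min(ts), t_end = max(ts),
               stringsAsFactors = FALSE)
  }))
  out$anchor_idx <- lapply(blocks, `[[`, "anchor_idx")
  out
}

emptyBlocks <- function() {
  out <- data.frame(block_id = integer(), orientation = character(),
                    n_anchors = integer(), q_start = numeric(),
                    q_end = numeric(), t_start = numeric(), t_end = numeric(),
                    stringsAsFactors = FALSE)
  out$anchor_idx <- list()
  out
}

#' DBSCAN density refinement of anchors in rank space
#'
#' Plain DBSCAN over anchors with Euclidean distance in the 2-D
#' (query rank, target rank) plane. Core points have at least `min_hits`
#' neighbours within `radius` (the point itself counts); border points are
#' assigned to the first core cluster in scan order; all remaining anchors
#' are noise and should be dropped before chaining.
#'
#' @param anchors data.frame/matrix with columns `q`, `t`.
#' @param radius neighbourhood radius in rank units (> 0).
#' @param min_hits minimum neighbours (incl. self) for a core point.
#' @return integer vector of cluster labels per anchor; 0 = noise.
#' @export
densityRefine <- function(anchors, radius = 50, min_hits = 10) {
  if (radius <= 0) stop("radius must be > 0")
  anchors <- as.data.frame(anchors)
  n <- nrow(anchors)
  if (n == 0) return(integer())
  names(anchors)[1:2] <- c("q", "t")
  d <- as.matrix(stats::dist(anchors[, c("q", "t")]))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= radius))
  core <- vapply(nb, length, integer(1)) >= min_hits
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || labels[i] != 0L) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      for (qq in nb[[p]]) {
        if (labels[qq] == 0L) {
          labels[qq] <- cl              # border or core joins first cluster
          if (core[qq]) queue <- c(queue, qq)
        }
      }
    }
  }
  labels
}

#' Count homeolog collinear blocks per off-diagonal chromosome pair
#'
#' Within-genome (self) similarity hits, pruned to pairs whose two genes
#' share an orthogroup, are mapped to gene-rank anchors for every unordered
#' pair of distinct chromosomes. Each pair's anchors are density-refined
#' (DBSCAN) and chained into collinear blocks; the total block count over
#' all off-diagonal pairs is the statistic that, corrected by the base
#' chromosome number, estimates the number of rearrangements since the
#' whole-genome duplication.
#'
#' @param genes gene-model table of one genome (with `rank`).
#' @param hits within-genome similarity hits.
#' @param orthogroups optional orthogroup table ([clusterOrthogroups()]
#'   output); when given, hits whose genes are in different orthogroups are
#'   discarded first.
#' @param params [chainParams()] list.
#' @return list with `per_pair` (data.frame: `chrom1`, `chrom2`,
#'   `n_blocks`) and `total`.
#' @export
countHomeologBlocks <- function(genes, hits, orthogroups = NULL,
                                params = chainParams()) {
  if (nrow(hits) == 0)
    return(list(per_pair = data.frame(chrom1 = character(),
                                      chrom2 = character(),
                                      n_blocks = integer()),
                total = 0L))
  hits <- hits[hits$query_genome == hits$target_genome &
                 hits$query_gene != hits$target_gene, , drop = FALSE]
  if (!is.null(orthogroups)) {
    og <- stats::setNames(orthogroups$og_id,
                          gene_key(orthogroups$genome, orthogroups$gene_id))
    same <- og[gene_key(hits$query_genome, hits$query_gene)] ==
      og[gene_key(hits$target_genome, hits$target_gene)]
    hits <- hits[!is.na(same) & same, , drop = FALSE]
  }
  ginfo <- genes[, c("gene_id", "chrom", "rank")]
  qi <- match(hits$query_gene, ginfo$gene_id)
  ti <- match(hits$target_gene, ginfo$gene_id)
  keep <- !is.na(qi) & !is.na(ti)
  hits <- hits[keep, , drop = FALSE]; qi <- qi[keep]; ti <- ti[keep]
  qc <- ginfo$chrom[qi]; tc <- ginfo$chrom[ti]
  off <- qc != tc
  qr <- ginfo$rank[qi]; tr <- ginfo$rank[ti]
  # canonical unordered chromosome pairs
  c1 <- ifelse(qc <= tc, qc, tc)
  c2 <- ifelse(qc <= tc, tc, qc)
  r1 <- ifelse(qc <= tc, qr, tr)
  r2 <- ifelse(qc <= tc, tr, qr)
  df <- unique(data.frame(c1 = c1[off], c2 = c2[off],
                          q = r1[off], t = r2[off],
                          stringsAsFactors = FALSE))
  if (nrow(df) == 0)
    return(list(per_pair = data.frame(chrom1 = character(),
                                      chrom2 = character(),
                                      n_blocks = integer()),
                total = 0L))
  pairs <- unique(df[, c("c1", "c2")])
  pairs <- pairs[order(pairs$c1, pairs$c2), , drop = FALSE]
  n_blocks <- vapply(seq_len(nrow(pairs)), function(i) {
    a <- df[df$c1 == pairs$c1[i] & df$c2 == pairs$c2[i], c("q", "t")]
    lab <- densityRefine(a, params$dbscan_radius, params$dbscan_min_hits)
    a <- a[lab > 0L, , drop = FALSE]
    if (nrow(a) == 0) return(0L)
    nrow(chainCollinearBlocks(a, params))
  }, integer(1))
  per_pair <- data.frame(chrom1 = pairs$c1, chrom2 = pairs$c2,
                         n_blocks = n_blocks, stringsAsFactors = FALSE)
  per_pair <- per_pair[per_pair$n_blocks > 0, , drop = FALSE]
  rownames(per_pair) <- NULL
  list(per_pair = per_pair, total = sum(n_blocks))
}

#' Average time between chromosomal rearrangements since the WGD
#'
#' The rearrangement count is the total homeolog collinear block count
#' corrected by the base chromosome number (`n_blocks - n_chroms`); the
#' interval is the WGD age divided by that count, reported to one decimal.
#' For pecan, 25 blocks over 16 chromosomes with a 60-Myr-old WGD gives one
#' rearrangement every 6.7 Myr. When no rearrangement has occurred
#' (`n_blocks == n_chroms`) the function returns `NA` with attribute
#' `n_rearrangements = 0` as the "no rearrangements" sentinel.
#'
#' @param n_blocks total homeolog collinear blocks (>= n_chroms).
#' @param n_chroms base chromosome number (>= 1).
#' @param wgd_age_myr age of the WGD in Myr (> 0).
#' @return Myr per rearrangement (one decimal), with attribute
#'   `n_rearrangements`; `NA_real_` when there are no rearrangements.
#' @export
rearrangementInterval <- function(n_blocks, n_chroms, wgd_age_myr) {
  if (n_chroms < 1) stop("n_chroms must be >= 1")
  if (wgd_age_myr <= 0) stop("wgd_age_myr must be > 0")
  if (n_blocks < n_chroms) stop("n_blocks must be >= n_chroms")
  n_re <- n_blocks - n_chroms
  out <- if (n_re == 0) NA_real_ else round(wgd_age_myr / n_re, 1)
  attr(out, "n_rearrangements") <- n_re
  out
}
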
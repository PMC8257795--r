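#' Prune variants before ancestry inference
#'
#' Filters applied in order: biallelic only, no missing calls (unless
#' `allow_missing`), minor allele count >= `min_minor_allele_count`, then
#' greedy left-to-right linkage-disequilibrium pruning: within each
#' chromosome a site is dropped when its genotype r^2 with any retained
#' site among the trailing `window` SNPs exceeds `max_r2` (the earlier
#' site is kept).
#'
#' @param gm a [GenotypeMatrix-class].
#' @param cfg a [pruneConfig()] list.
#' @return the pruned [GenotypeMatrix-class] (a warning, not an error, if
#'   nothing survives).
#' @export
pruneVariants <- function(gm, cfg = pruneConfig()) {
  sites <- siteInfo(gm); calls <- genotypeCalls(gm)
  n_samp <- length(sampleIds(gm))
  keep <- !sites$multiallelic
  if (!cfg$allow_missing) keep <- keep & colSums(is.na(calls)) == 0
  ref_ac <- colSums(calls, na.rm = TRUE)
  tot_ac <- 2 * colSums(!is.na(calls))
  mac <- pmin(ref_ac, tot_ac - ref_ac)
  keep <- keep & mac >= cfg$min_minor_allele_count
  idx <- which(keep)
  # LD pruning within trailing windows, per chromosome, position order
  retained <- integer()
  for (ch in unique(sites$chrom[idx])) {
    ci <- idx[sites$chrom[idx] == ch]
    ci <- ci[order(sites$pos[ci])]
    kept_ch <- integer()
    for (j in ci) {
      win <- utils::tail(kept_ch, cfg$window - 1L)
      drop <- FALSE
      if (length(win)) {
        r2 <- suppressWarnings(
          stats::cor(calls[, j], calls[, win, drop = FALSE],
                     use = "pairwise.complete.obs"))^2
        drop <- any(r2 > cfg$max_r2, na.rm = TRUE)
      }
      if (!drop) kept_ch <- c(kept_ch, j)
    }
    retained <- c(retained, kept_ch)
  }
  retained <- sort(retained)
  if (!length(retained)) warning("no variants survive pruning")
  GenotypeMatrix(sampleIds(gm), sites[retained, , drop = FALSE],
                 genotypeCalls(gm)[, retained, drop = FALSE],
                 if (!is.null(readDepth(gm)))
                   readDepth(gm)[, retained, drop = FALSE])
}

#' Per-source allele frequencies with pseudocounts
#'
#' Reference-allele frequency per site per source population, with a
#' pseudocount of 0.5 per allele so no frequency is exactly 0 or 1.
#'
#' @param gm a [GenotypeMatrix-class] containing the source samples.
#' @param populations named character vector: sample id -> population.
#' @return matrix, sites x populations, of reference-allele frequencies.
#' @export
sourceFrequencies <- function(gm, populations) {
  calls <- genotypeCalls(gm)
  pops <- unique(populations)
  out <- sapply(pops, function(p) {
    rows <- which(sampleIds(gm) %in% names(populations)[populations == p])
    sub <- calls[rows, , drop = FALSE]
    (colSums(sub, na.rm = TRUE) + 0.5) /
      (2 * colSums(!is.na(sub)) + 1)
  })
  colnames(out) <- pops
  out
}

#' Global ancestry proportions by non-negative least squares
#'
#' Regresses a test sample's allele-frequency vector (genotype / 2) on the
#' source allele-frequency vectors with non-negativity constraints and
#' normalises the coefficients to sum to 1. If all sources have identical
#' frequencies the problem is non-identifiable and a uniform vector is
#' returned with a warning.
#'
#' @param sample_geno reference-allele counts of the test sample (vector,
#'   one per site; NAs dropped).
#' @param source_freqs sites x sources matrix of reference-allele
#'   frequencies.
#' @return named numeric vector of proportions summing to 1.
#' @export
globalAncestry <- function(sample_geno, source_freqs) {
  source_freqs <- as.matrix(source_freqs)
  if (ncol(source_freqs) < 2) stop("need at least 2 sources")
  ok <- !is.na(sample_geno) & rowSums(is.na(source_freqs)) == 0
  y <- sample_geno[ok] / 2
  A <- source_freqs[ok, , drop = FALSE]
  if (all(apply(A, 1, function(r) max(r) - min(r)) < 1e-12)) {
    warning("all sources have identical frequencies; returning uniform")
    p <- rep(1 / ncol(A), ncol(A))
    names(p) <- colnames(A)
    return(p)
  }
  fit <- pracma::lsqnonneg(A, y)
  x <- fit$x
  if (sum(x) <= 0) {
    warning("degenerate NNLS fit; returning uniform")
    x <- rep(1, ncol(A))
  }
  p <- x / sum(x)
  names(p) <- colnames(A)
  p
}

#' Scaled forward-backward posterior decoding
#'
#' Generic forward-backward over a discrete-state hidden Markov chain with
#' per-step transition matrices and per-marker emission likelihoods, using
#' per-step scaling. Exported so small chains can be checked against
#' exhaustive path-sum enumeration.
#'
#' @param init initial state distribution (length K).
#' @param trans list of (T-1) K x K transition matrices, or a single matrix
#'   used for every step.
#' @param emiss T x K matrix of emission likelihoods.
#' @return list `posterior` (T x K, rows sum to 1) and `loglik`.
#' @export
forwardBackward <- function(init, trans, emiss) {
  T_ <- nrow(emiss); K <- ncol(emiss)
  stopifnot(length(init) == K)
  get_tr <- function(t) if (is.list(trans)) trans[[t]] else trans
  alpha <- matrix(0, T_, K); scale <- numeric(T_)
  a <- init * emiss[1, ]
  scale[1] <- sum(a)
  alpha[1, ] <- a / scale[1]
  if (T_ > 1) for (t in 2:T_) {
    a <- as.numeric(alpha[t - 1, ] %*% get_tr(t - 1)) * emiss[t, ]
    scale[t] <- sum(a)
    alpha[t, ] <- a / scale[t]
  }
  beta <- matrix(0, T_, K)
  beta[T_, ] <- 1
  if (T_ > 1) for (t in (T_ - 1):1) {
    b <- as.numeric(get_tr(t) %*% (emiss[t + 1, ] * beta[t + 1, ]))
    beta[t, ] <- b / scale[t + 1]
  }
  post <- alpha * beta
  post <- post / rowSums(post)
  list(posterior = post, loglik = sum(log(scale)))
}

state_pairs <- function(K) {
  pairs <- which(upper.tri(matrix(0, K, K), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  cbind(a = pairs[, "row"], b = pairs[, "col"])
}

#' Local-ancestry posterior probabilities
#'
#' Hidden Markov model over diploid ancestry states (unordered source
#' pairs; 10 states for 4 sources). Emissions: given state (a, b) the two
#' alleles are independent Bernoulli draws at the source reference-allele
#' frequencies, each misread with probability `genotyping_error`.
#' Transitions: each haplotype switches ancestry over an inter-marker
#' distance of d morgans with probability 1 - exp(-switch_rate * d), and a
#' switching haplotype draws its new ancestry from the prior proportions.
#' Decoded by scaled forward-backward; posterior rows sum to 1.
#'
#' @param sample_geno reference-allele counts (0/1/2/NA), ordered by
#'   position.
#' @param source_freqs sites x sources matrix of reference-allele
#'   frequencies (columns named by source).
#' @param pos_morgans marker positions on the genetic map, in morgans,
#'   non-decreasing.
#' @param cfg a [hmmConfig()] list.
#' @param positions_bp optional physical positions stored alongside.
#' @param chrom chromosome label.
#' @return An [AncestryPosterior-class] object.
#' @export
ancestryPosteriors <- function(sample_geno, source_freqs, pos_morgans,
                               cfg = hmmConfig(), positions_bp = NULL,
                               chrom = "chr1") {
  source_freqs <- as.matrix(source_freqs)
  K <- ncol(source_freqs)
  stopifnot(K == cfg$n_sources)
  T_ <- length(sample_geno)
  stopifnot(nrow(source_freqs) == T_, length(pos_morgans) == T_)
  if (T_ > 1 && any(diff(pos_morgans) < 0))
    stop("marker positions must be non-decreasing")
  if (is.null(positions_bp)) positions_bp <- seq_len(T_)
  src <- colnames(source_freqs)
  if (is.null(src)) src <- as.character(seq_len(K) - 1L)
  pairs <- state_pairs(K)
  labels <- paste(src[pairs[, "a"]], src[pairs[, "b"]], sep = "/")
  e <- cfg$genotyping_error
  pi_ <- cfg$ancestry_priors
  # emission likelihoods per unordered state
  f_err <- source_freqs * (1 - e) + (1 - source_freqs) * e
  emiss <- matrix(1, T_, nrow(pairs))
  gobs <- sample_geno
  for (s in seq_len(nrow(pairs))) {
    fa <- f_err[, pairs[s, "a"]]; fb <- f_err[, pairs[s, "b"]]
    p2 <- fa * fb
    p1 <- fa * (1 - fb) + fb * (1 - fa)
    p0 <- (1 - fa) * (1 - fb)
    lik <- rep(1, T_)
    lik[!is.na(gobs) & gobs == 2] <- p2[!is.na(gobs) & gobs == 2]
    lik[!is.na(gobs) & gobs == 1] <- p1[!is.na(gobs) & gobs == 1]
    lik[!is.na(gobs) & gobs == 0] <- p0[!is.na(gobs) & gobs == 0]
    emiss[, s] <- lik
  }
  # per-haplotype transition: (1-s) I + s * pi; diploid = product over the
  # two haplotypes, collapsed onto unordered pairs
  hap_trans <- function(d) {
    s <- 1 - exp(-cfg$switch_rate * d)
    (1 - s) * diag(K) + s * matrix(pi_, K, K, byrow = TRUE)
  }
  collapse <- function(Tm) {
    # Tm: K^2 ordered transition as kronecker; build unordered-state matrix
    S <- nrow(pairs)
    out <- matrix(0, S, S)
    for (i in seq_len(S)) {
      a <- pairs[i, "a"]; b <- pairs[i, "b"]
      for (j in seq_len(S)) {
        c_ <- pairs[j, "a"]; d_ <- pairs[j, "b"]
        # from ordered (a,b): to unordered {c,d}
        p <- Tm[a, c_] * Tm[b, d_]
        if (c_ != d_) p <- p + Tm[a, d_] * Tm[b, c_]
        out[i, j] <- p
      }
    }
    out
  }
  d <- diff(pos_morgans)
  uniq_d <- unique(d)
  tr_cache <- lapply(uniq_d, function(dd) collapse(hap_trans(dd)))
  names(tr_cache) <- as.character(uniq_d)
  trans <- lapply(d, function(dd) tr_cache[[as.character(dd)]])
  init <- pi_[pairs[, "a"]] * pi_[pairs[, "b"]] *
    ifelse(pairs[, "a"] == pairs[, "b"], 1, 2)
  fb <- forwardBackward(init, trans, emiss)
  new("AncestryPosterior", prob = fb$posterior, states = labels,
      positions = as.numeric(positions_bp), chrom = chrom, priors = init)
}

#' Decode and cull ancestry blocks
#'
#' Hard calls are the per-marker argmax state (ties resolved towards the
#' state with the larger prior, then the lower state index). Runs of
#' identical calls are then iteratively culled: for L = 2, 3, ...,
#' `min_block`, any maximal run shorter than L (processed left to right)
#' is reassigned to the flanking run with more markers (ties to the left
#' flank), until no run shorter than `min_block` remains. The surviving
#' maximal runs are returned as blocks; they tile the chromosome.
#'
#' @param post an [AncestryPosterior-class].
#' @param min_block minimum run length in markers (default 500).
#' @return data.frame `state`, `start_idx`, `end_idx`, `n_markers`,
#'   `start_bp`, `end_bp`, `mean_posterior`.
#' @export
decodeAndCull <- function(post, min_block = 500) {
  if (min_block < 2) stop("min_block must be >= 2")
  prob <- posteriorProb(post)
  priors <- post@priors
  T_ <- nrow(prob)
  calls <- vapply(seq_len(T_), function(t) {
    p <- prob[t, ]
    cand <- which(p >= max(p) - 1e-12)
    if (length(cand) > 1) {
      cand <- cand[priors[cand] == max(priors[cand])]
    }
    cand[1]
  }, integer(1))
  calls <- cullRuns(calls, min_block)
  r <- rle(calls)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  data.frame(
    state = ancestryStates(post)[r$values],
    start_idx = starts, end_idx = ends, n_markers = r$lengths,
    start_bp = post@positions[starts], end_bp = post@positions[ends],
    mean_posterior = vapply(seq_along(starts), function(k)
      mean(prob[starts[k]:ends[k], r$values[k]]), numeric(1)),
    stringsAsFactors = FALSE)
}

# iterative run culling shared by decodeAndCull (kept separate so the
# recurrence can be tested directly)
cullRuns <- function(calls, min_block) {
  for (L in 2:min_block) {
    repeat {
      r <- rle(calls)
      short <- which(r$lengths < L)
      if (!length(short)) break
      if (length(r$lengths) == 1) break
      i <- short[1]
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      left_n <- if (i > 1) r$lengths[i - 1] else -1L
      right_n <- if (i < length(r$lengths)) r$lengths[i + 1] else -1L
      new_val <- if (left_n >= right_n) r$values[i - 1] else r$values[i + 1]
      calls[starts[i]:ends[i]] <- new_val
    }
    if (length(unique(calls)) == 1) break
  }
  calls
}

#' High-confidence introgression intervals across relatives
#'
#' For each donor source, intersects the physical intervals with
#' non-background ancestry (any decoded block whose state includes the
#' donor) across the reference genotype and all of its relatives; only
#' regions introgressed in every related genotype survive.
#'
#' @param blocks_per_sample named list of [decodeAndCull()] outputs; the
#'   first element is the reference genotype, the rest its relatives (at
#'   least one required).
#' @param background the background (recipient) source label.
#' @return data.frame `donor`, `start_bp`, `end_bp`.
#' @export
highConfidenceIntrogressions <- function(blocks_per_sample, background) {
  if (length(blocks_per_sample) < 2)
    stop("need the reference genotype plus at least one relative")
  donors <- unique(unlist(lapply(blocks_per_sample, function(b)
    setdiff(unlist(strsplit(b$state, "/", fixed = TRUE)), background))))
  out <- list()
  for (don in donors) {
    ir <- NULL
    for (b in blocks_per_sample) {
      has <- vapply(strsplit(b$state, "/", fixed = TRUE),
                    function(s) don %in% s, logical(1))
      sub <- b[has, , drop = FALSE]
      cur <- IRanges::reduce(IRanges::IRanges(start = sub$start_bp,
                                              end = sub$end_bp))
      ir <- if (is.null(ir)) cur else IRanges::intersect(ir, cur)
      if (length(ir) == 0) break
    }
    if (!is.null(ir) && length(ir))
      out[[don]] <- data.frame(donor = don,
                               start_bp = IRanges::start(ir),
                               end_bp = IRanges::end(ir),
                               stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(donor = character(), start_bp = numeric(),
                      end_bp = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarise introgression intervals per donor
#'
#' @param intervals output of [highConfidenceIntrogressions()] (bp).
#' @param genome_size_mb genome size in Mb.
#' @return data.frame `donor`, `mb`, `pct` (100 x Mb / genome size).
#' @export
introgressionSummary <- function(intervals, genome_size_mb) {
  stopifnot(genome_size_mb > 0)
  if (nrow(intervals) == 0)
    return(data.frame(donor = character(), mb = numeric(), pct = numeric()))
  len_mb <- (intervals$end_bp - intervals$start_bp + 1) / 1e6
  agg <- tapply(len_mb, intervals$donor, sum)
  data.frame(donor = names(agg), mb = as.numeric(agg),
             pct = 100 * as.numeric(agg) / genome_size_mb,
             stringsAsFactors = FALSE, row.names = NULL)
}
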
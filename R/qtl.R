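#' Kosambi map function and its inverse
#'
#' `kosambiD` converts a recombination fraction r to map distance
#' d = 25 ln((1+2r)/(1-2r)) cM; `kosambiR` inverts it
#' (r = tanh(d/50) / 2).
#'
#' @param r recombination fraction in \[0, 0.5).
#' @param d map distance in cM.
#' @return numeric vector.
#' @export
kosambiD <- function(r) 25 * log((1 + 2 * r) / (1 - 2 * r))

#' @rdname kosambiD
#' @export
kosambiR <- function(d) 0.5 * tanh(d / 50)

#' Filter markers for pseudo-testcross linkage analysis
#'
#' Sites are removed when the minor allele frequency is below `min_maf`,
#' the heterozygous call frequency exceeds `max_het_freq`, the missing
#' call frequency exceeds `max_missing`, or more than `max_alleles`
#' alleles were observed (all strict inequalities, as quoted thresholds).
#' Finally the `depth_trim_fraction` of loci with the highest and lowest
#' mean read depths are discarded (when depths are available).
#'
#' @param gm a [GenotypeMatrix-class].
#' @param cfg a [markerFilterConfig()] list.
#' @return the filtered [GenotypeMatrix-class].
#' @export
filterMarkers <- function(gm, cfg = markerFilterConfig()) {
  calls <- genotypeCalls(gm); sites <- siteInfo(gm)
  n_obs <- colSums(!is.na(calls))
  ref_ac <- colSums(calls, na.rm = TRUE)
  af <- ifelse(n_obs > 0, ref_ac / (2 * n_obs), NA)
  maf <- pmin(af, 1 - af)
  het <- colMeans(calls == 1, na.rm = TRUE)
  miss <- colMeans(is.na(calls))
  keep <- !is.na(maf) & maf >= cfg$min_maf & het <= cfg$max_het_freq &
    miss <= cfg$max_missing
  if (cfg$max_alleles <= 2) keep <- keep & !sites$multiallelic
  dp <- readDepth(gm)
  if (!is.null(dp) && cfg$depth_trim_fraction > 0) {
    md <- colMeans(dp, na.rm = TRUE)
    qs <- stats::quantile(md, c(cfg$depth_trim_fraction,
                                1 - cfg$depth_trim_fraction), na.rm = TRUE)
    keep <- keep & md > qs[1] & md < qs[2]
  }
  idx <- which(keep)
  GenotypeMatrix(sampleIds(gm), sites[idx, , drop = FALSE],
                 calls[, idx, drop = FALSE],
                 if (!is.null(dp)) dp[, idx, drop = FALSE])
}

#' Phase pseudo-testcross markers into two parental haplotypes
#'
#' Markers informative in the focal (heterozygous) parent are clustered
#' into two phases per chromosome by the sign of their pairwise genotype
#' correlations (greedy seed-and-extend: the first marker seeds phase 1;
#' each following marker joins the phase maximising the absolute mean
#' signed agreement with already-phased markers). Phase labels are then
#' mapped to parent-of-origin via the grandparental genotype table: the
#' haplotype carrying the alternate alleles attributed to the first origin
#' level becomes haplotype "A" (coded 1).
#'
#' @param x progeny x marker matrix of alternate-allele inheritance
#'   (1 = progeny inherited the focal parent's alternate allele, 0 =
#'   reference, NA = missing); columns named by marker.
#' @param markers data.frame `marker`, `chrom`, `pos_bp` (ordered or not).
#' @param parental_origin named character vector: marker -> origin of its
#'   alternate allele (e.g. "Mahan" / "Major").
#' @param origin_levels the two origin labels; the first defines
#'   haplotype A.
#' @return A [CrossGenotypes-class]; `markers$phase` holds
#'   "<origin>-like" labels.
#' @export
phaseTestcross <- function(x, markers, parental_origin,
                           origin_levels = NULL) {
  stopifnot(ncol(x) == nrow(markers))
  if (is.null(colnames(x))) colnames(x) <- markers$marker
  if (is.null(origin_levels))
    origin_levels <- sort(unique(parental_origin))
  stopifnot(length(origin_levels) == 2)
  ord <- order(markers$chrom, markers$pos_bp, markers$marker)
  markers <- markers[ord, , drop = FALSE]
  x <- x[, ord, drop = FALSE]
  phase <- integer(nrow(markers))
  for (ch in unique(markers$chrom)) {
    j <- which(markers$chrom == ch)
    if (length(j) < 2)
      stop("chromosome ", ch, " has fewer than 2 informative markers")
    xc <- x[, j, drop = FALSE]
    cc <- suppressWarnings(stats::cor(xc, use = "pairwise.complete.obs"))
    ph <- integer(length(j)); ph[1] <- 1L
    for (k in 2:length(j)) {
      done <- which(ph != 0L)
      sc <- mean(ph[done] * cc[k, done], na.rm = TRUE)
      ph[k] <- if (!is.na(sc) && sc < 0) -1L else 1L
    }
    phase[j] <- ph
  }
  # map clusters to parent-of-origin per chromosome (cluster labels are
  # arbitrary within each chromosome): orient so haplotype "A" (coded 1)
  # is the one carrying the alt alleles attributed to origin_levels[1]
  org <- parental_origin[markers$marker]
  a <- x
  for (ch in unique(markers$chrom)) {
    j <- which(markers$chrom == ch)
    vote1 <- sum(org[j] == origin_levels[1] & phase[j] == 1L, na.rm = TRUE) +
      sum(org[j] == origin_levels[2] & phase[j] == -1L, na.rm = TRUE)
    vote2 <- sum(org[j] == origin_levels[2] & phase[j] == 1L, na.rm = TRUE) +
      sum(org[j] == origin_levels[1] & phase[j] == -1L, na.rm = TRUE)
    if (vote2 > vote1) phase[j] <- -phase[j]
    # haplotype-consistent coding: 1 = inherited the oriented +1 haplotype
    flip <- j[phase[j] == -1L]
    a[, flip] <- 1L - a[, flip]
  }
  markers$phase <- ifelse(phase == 1L, paste0(origin_levels[1], "-like"),
                          paste0(origin_levels[2], "-like"))
  markers$cM <- NA_real_
  rn <- rownames(x); if (is.null(rn)) rn <- paste0("p", seq_len(nrow(x)))
  CrossGenotypes(a, markers[, c("marker", "chrom", "pos_bp", "cM", "phase")], rn)
}

#' Bin markers to one per phase and physical bin
#'
#' Within each (phase, `bin_size`-bp bin) the marker whose progeny
#' genotype vector best agrees with the mean local haplotype (the majority
#' call over up to `local_window` markers up- and downstream) is kept;
#' agreement ties keep the lower physical coordinate.
#'
#' @param cg a [CrossGenotypes-class] (haplotype-coded, so phases are
#'   directly comparable).
#' @param bin_size bin width in bp (default 25,000).
#' @param local_window flanking markers per side used for the local
#'   haplotype (default 10).
#' @return the binned [CrossGenotypes-class].
#' @export
binMarkers <- function(cg, bin_size = 25000, local_window = 10) {
  mk <- markerInfo(cg); g <- crossGeno(cg)
  keep <- logical(nrow(mk))
  for (ch in unique(mk$chrom)) {
    j <- which(mk$chrom == ch)
    j <- j[order(mk$pos_bp[j])]
    agree <- vapply(seq_along(j), function(k) {
      nb <- j[setdiff(max(1, k - local_window):min(length(j), k + local_window), k)]
      if (!length(nb)) return(0)
      m <- rowMeans(g[, nb, drop = FALSE], na.rm = TRUE)
      maj <- ifelse(m > 0.5, 1L, ifelse(m < 0.5, 0L, NA_integer_))
      call <- g[, j[k]]
      ok <- !is.na(call)
      credit <- ifelse(is.na(maj[ok]), 0.5, as.numeric(call[ok] == maj[ok]))
      if (!length(credit)) 0 else mean(credit)
    }, numeric(1))
    bin <- floor(mk$pos_bp[j] / bin_size)
    grp <- paste(mk$phase[j], bin, sep = "\r")
    for (idx in split(seq_along(j), grp)) {
      o <- order(-agree[idx], mk$pos_bp[j[idx]])
      keep[j[idx[o[1]]]] <- TRUE
    }
  }
  idx <- which(keep)
  CrossGenotypes(g[, idx, drop = FALSE], mk[idx, , drop = FALSE], cg@progeny)
}

#' Estimate a genetic map with the Kosambi function
#'
#' Adjacent-marker recombination fractions are estimated from observed
#' mismatch frequencies under a symmetric genotyping-error model
#' (P(observed mismatch) = r((1-e)^2 + e^2) + (1-r) 2e(1-e), inverted at
#' the maximum-likelihood point and clamped to \[0, 0.4999\]), then
#' converted to cM with the Kosambi map function and accumulated per
#' chromosome. Adjacent pairs with no co-observed progeny are flagged
#' unlinked (r clamped at the cap).
#'
#' @param cg a [CrossGenotypes-class].
#' @param error_prob genotyping error probability (default 0.0165).
#' @return the [CrossGenotypes-class] with `markers$cM` filled; attribute
#'   `unlinked` lists flagged adjacencies.
#' @export
estimateMap <- function(cg, error_prob = 0.0165) {
  mk <- markerInfo(cg); g <- crossGeno(cg)
  e <- error_prob
  unlinked <- character()
  for (ch in unique(mk$chrom)) {
    j <- which(mk$chrom == ch)
    j <- j[order(mk$pos_bp[j])]
    cm <- numeric(length(j)); cm[1] <- 0
    if (length(j) > 1) for (k in 2:length(j)) {
      g1 <- g[, j[k - 1]]; g2 <- g[, j[k]]
      ok <- !is.na(g1) & !is.na(g2)
      if (!any(ok)) {
        r <- 0.4999
        unlinked <- c(unlinked, paste(mk$marker[j[k - 1]], mk$marker[j[k]],
                                      sep = "--"))
      } else {
        m_obs <- mean(g1[ok] != g2[ok])
        r <- (m_obs - 2 * e * (1 - e)) / (1 - 2 * e)^2
        r <- min(max(r, 0), 0.4999)
      }
      cm[k] <- cm[k - 1] + kosambiD(r)
    }
    mk$cM[j] <- cm
  }
  out <- CrossGenotypes(g, mk, cg@progeny)
  attr(out, "unlinked") <- unlinked
  out
}

# error-aware two-point genotype probabilities P(haplotype A) on a cM grid
# for one chromosome. geno: progeny x markers (0/1/NA), cm: marker cM,
# grid: positions. Returns progeny x length(grid).
genoprob_chrom <- function(geno, cm, grid, error_prob) {
  n <- nrow(geno); e <- error_prob
  out <- matrix(0.5, n, length(grid))
  w <- function(obs, t) ifelse(obs == t, 1 - e, e)
  if (!anyNA(geno)) {
    # fast path: every progeny shares the same flanking markers
    left_idx <- findInterval(grid, cm)
    for (p in seq_along(grid)) {
      li <- left_idx[p]; ri <- li + 1L
      hasL <- li >= 1L; hasR <- ri <= length(cm)
      if (hasL && hasR) {
        rL <- kosambiR(grid[p] - cm[li]); rR <- kosambiR(cm[ri] - grid[p])
        oL <- geno[, li]; oR <- geno[, ri]
        num <- den <- rep(0, n)
        for (tp in c(1L, 0L)) {
          s <- rep(0, n)
          for (tL in c(0L, 1L)) for (tR in c(0L, 1L)) {
            s <- s + 0.5 * w(oL, tL) *
              (if (tL == tp) 1 - rL else rL) *
              (if (tp == tR) 1 - rR else rR) * w(oR, tR)
          }
          if (tp == 1L) num <- s
          den <- den + s
        }
        out[, p] <- num / den
      } else if (hasL || hasR) {
        ki <- if (hasL) li else ri
        rr <- kosambiR(abs(grid[p] - cm[ki]))
        pA <- w(geno[, ki], 1L) * 0.5
        pA <- pA / (pA + w(geno[, ki], 0L) * 0.5)
        out[, p] <- pA * (1 - rr) + (1 - pA) * rr
      }
    }
    return(out)
  }
  for (i in seq_len(n)) {
    obs <- geno[i, ]
    known <- which(!is.na(obs))
    if (!length(known)) next
    km <- cm[known]; ko <- obs[known]
    left_idx <- findInterval(grid, km)           # last known <= grid pos
    for (p in seq_along(grid)) {
      li <- left_idx[p]
      ri <- li + 1L
      hasL <- li >= 1L; hasR <- ri <= length(known)
      if (hasL && hasR) {
        rL <- kosambiR(grid[p] - km[li]); rR <- kosambiR(km[ri] - grid[p])
        num <- 0; den <- 0
        for (tp in c(1L, 0L)) {
          s <- 0
          for (tL in c(0L, 1L)) for (tR in c(0L, 1L)) {
            s <- s + 0.5 * w(ko[li], tL) *
              (if (tL == tp) 1 - rL else rL) *
              (if (tp == tR) 1 - rR else rR) * w(ko[ri], tR)
          }
          if (tp == 1L) num <- s
          den <- den + s
        }
        out[i, p] <- num / den
      } else if (hasL || hasR) {
        ki <- if (hasL) li else ri
        rr <- kosambiR(abs(grid[p] - km[ki]))
        pA <- w(ko[ki], 1L) * 0.5; pB <- w(ko[ki], 0L) * 0.5
        pA <- pA / (pA + pB)
        out[i, p] <- pA * (1 - rr) + (1 - pA) * rr
      }
    }
  }
  out
}

# restricted log-likelihood of the null (intercept-only) model in the
# rotated eigenspace, profiled over sigma^2, for a grid of heritabilities.
# ystar: rotated phenotype matrix (n x P); u0: rotated intercept; lambda:
# eigenvalues. Returns list(h2: best per column, rss0: null RSS at best h2)
null_h2_fit <- function(ystar, u0, lambda, grid = seq(0, 0.99, by = 0.01)) {
  n <- nrow(ystar); P <- ncol(ystar)
  best_ll <- rep(-Inf, P); best_h2 <- numeric(P); best_rss <- numeric(P)
  for (h2 in grid) {
    wgt <- h2 * lambda + (1 - h2)
    iw <- 1 / wgt
    a0 <- sum(u0^2 * iw)
    b0 <- as.numeric(crossprod(u0 * iw, ystar))
    yy <- as.numeric(crossprod(iw, ystar^2))
    rss <- pmax(yy - b0^2 / a0, 1e-12)
    ll <- -0.5 * ((n - 1) * log(rss) + sum(log(wgt)) + log(a0))
    upd <- ll > best_ll
    best_ll[upd] <- ll[upd]; best_h2[upd] <- h2; best_rss[upd] <- rss[upd]
  }
  list(h2 = best_h2, rss0 = best_rss)
}

loco_kinship <- function(geno, chroms) {
  g <- geno
  cm <- colMeans(g, na.rm = TRUE)
  for (j in seq_len(ncol(g))) g[is.na(g[, j]), j] <- cm[j]
  g <- scale(g, center = TRUE, scale = FALSE)
  out <- list()
  for (ch in unique(chroms)) {
    keep <- chroms != ch
    m <- sum(keep)
    out[[ch]] <- if (m > 0) tcrossprod(g[, keep, drop = FALSE]) / m
    else diag(nrow(g)) * 0
  }
  out
}

#' Genome scan with a LOCO linear mixed model
#'
#' Pseudomarkers are inserted every `cfg$step` cM and their haplotype
#' probabilities computed by error-aware two-point interpolation from the
#' flanking observed markers. Per chromosome, a leave-one-chromosome-out
#' kinship matrix (centred genotype cross-product) is eigendecomposed, the
#' null heritability is fit on a 0.01 grid by restricted likelihood, and
#' LOD = (n/2) log10(RSS0/RSS1) is computed by generalised least squares in
#' the rotated model at every position.
#'
#' @param cg a [CrossGenotypes-class] with an estimated map.
#' @param phenotype numeric vector, one value per progeny.
#' @param cfg a [scanConfig()] list.
#' @return list: `profile` (data.frame `chrom`, `cM`, `pos_bp`, `lod`),
#'   `peak` (row of profile), `h2` (per chromosome), `n`.
#' @export
scanLod <- function(cg, phenotype, cfg = scanConfig()) {
  mk <- markerInfo(cg); g <- crossGeno(cg)
  if (all(is.na(mk$cM))) stop("markers have no cM positions; run estimateMap()")
  if (stats::sd(phenotype, na.rm = TRUE) == 0 || all(is.na(phenotype)))
    stop("constant phenotype")
  n <- length(phenotype)
  stopifnot(n == nrow(g))
  kin <- if (cfg$kinship == "loco") loco_kinship(g, mk$chrom) else NULL
  chroms <- unique(mk$chrom)
  prof <- list(); h2s <- stats::setNames(numeric(length(chroms)), chroms)
  for (ch in chroms) {
    j <- which(mk$chrom == ch)
    j <- j[order(mk$cM[j])]
    cm <- mk$cM[j]
    grid <- sort(unique(c(cm, seq(0, max(cm), by = cfg$step))))
    gp <- genoprob_chrom(g[, j, drop = FALSE], cm, grid, cfg$error_prob)
    if (is.null(kin)) {
      U <- diag(n); lambda <- rep(0, n)
    } else {
      eig <- eigen(kin[[ch]], symmetric = TRUE)
      U <- eig$vectors; lambda <- pmax(eig$values, 0)
    }
    ystar <- crossprod(U, matrix(phenotype, ncol = 1))
    u0 <- as.numeric(crossprod(U, rep(1, n)))
    fit <- null_h2_fit(ystar, u0, lambda)
    h2 <- fit$h2[1]; rss0 <- fit$rss0[1]
    h2s[ch] <- h2
    wgt <- h2 * lambda + (1 - h2); iw <- 1 / wgt
    y <- as.numeric(ystar)
    lods <- vapply(seq_along(grid), function(p) {
      x <- as.numeric(crossprod(U, gp[, p]))
      a11 <- sum(u0^2 * iw); a12 <- sum(u0 * x * iw); a22 <- sum(x^2 * iw)
      b1 <- sum(u0 * y * iw); b2 <- sum(x * y * iw)
      det <- a11 * a22 - a12^2
      if (det < 1e-12) return(0)
      beta1 <- (a22 * b1 - a12 * b2) / det
      beta2 <- (-a12 * b1 + a11 * b2) / det
      rss1 <- sum(y^2 * iw) - (b1 * beta1 + b2 * beta2)
      rss1 <- max(rss1, 1e-12)
      max(0, n / 2 * log10(rss0 / rss1))
    }, numeric(1))
    # physical positions by linear interpolation of the marker cM -> bp map
    bp <- stats::approx(x = cm, y = mk$pos_bp[j], xout = grid, rule = 2,
                        ties = "ordered")$y
    prof[[ch]] <- data.frame(chrom = ch, cM = grid, pos_bp = bp, lod = lods,
                             stringsAsFactors = FALSE)
  }
  profile <- do.call(rbind, prof)
  rownames(profile) <- NULL
  peak <- profile[which.max(profile$lod), , drop = FALSE]
  list(profile = profile, peak = peak, h2 = h2s, n = n)
}

#' Genome-wide LOD significance threshold by permutation
#'
#' The phenotype is permuted `cfg$n_permutations` times (seeded via
#' `cfg$seed`); for each permutation the genome-wide maximum LOD over the
#' marker frame is recorded (null heritability refit per permutation and
#' chromosome), and the threshold is the 95th percentile of those maxima.
#'
#' @inheritParams scanLod
#' @param alpha genome-wide type-I error (default 0.05).
#' @return list `threshold`, `max_lods` (one per permutation).
#' @export
permutationThreshold <- function(cg, phenotype, cfg = scanConfig(),
                                 alpha = 0.05) {
  if (cfg$n_permutations == 0) stop("n_permutations must be > 0")
  if (cfg$n_permutations < 100)
    warning("fewer than 100 permutations gives an unstable threshold")
  mk <- markerInfo(cg); g <- crossGeno(cg)
  n <- length(phenotype)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  P <- cfg$n_permutations
  Y <- vapply(seq_len(P), function(i) sample(phenotype), numeric(n))
  kin <- if (cfg$kinship == "loco") loco_kinship(g, mk$chrom) else NULL
  maxlod <- rep(0, P)
  for (ch in unique(mk$chrom)) {
    j <- which(mk$chrom == ch)
    j <- j[order(mk$cM[j])]
    cm <- mk$cM[j]
    gp <- genoprob_chrom(g[, j, drop = FALSE], cm, cm, cfg$error_prob)
    if (is.null(kin)) {
      U <- diag(n); lambda <- rep(0, n)
    } else {
      eig <- eigen(kin[[ch]], symmetric = TRUE)
      U <- eig$vectors; lambda <- pmax(eig$values, 0)
    }
    Ystar <- crossprod(U, Y)
    u0 <- as.numeric(crossprod(U, rep(1, n)))
    fit <- null_h2_fit(Ystar, u0, lambda)
    Xr <- crossprod(U, gp)        # rotated genotype probs, n x positions
    for (h2 in unique(fit$h2)) {
      cols <- which(fit$h2 == h2)
      wgt <- h2 * lambda + (1 - h2); iw <- 1 / wgt
      Ysub <- Ystar[, cols, drop = FALSE]
      yy <- as.numeric(crossprod(iw, Ysub^2))
      a11 <- sum(u0^2 * iw)
      B1 <- as.numeric(crossprod(u0 * iw, Ysub))
      rss0 <- fit$rss0[cols]
      for (p in seq_len(ncol(Xr))) {
        x <- Xr[, p]
        a12 <- sum(u0 * x * iw); a22 <- sum(x^2 * iw)
        det <- a11 * a22 - a12^2
        if (det < 1e-12) next
        B2 <- as.numeric(crossprod(x * iw, Ysub))
        beta1 <- (a22 * B1 - a12 * B2) / det
        beta2 <- (-a12 * B1 + a11 * B2) / det
        rss1 <- pmax(yy - (B1 * beta1 + B2 * beta2), 1e-12)
        lod <- n / 2 * log10(rss0 / rss1)
        maxlod[cols] <- pmax(maxlod[cols], lod)
      }
    }
  }
  list(threshold = stats::quantile(maxlod, 1 - alpha, names = FALSE),
       max_lods = maxlod)
}

#' Bayes credible interval for a QTL peak
#'
#' On the peak chromosome, 10^LOD is normalised over positions and the
#' smallest contiguous run of positions containing the peak whose mass
#' reaches `prob` is returned; interval ends are projected to physical
#' coordinates through the profile's cM -> bp interpolation.
#'
#' @param profile the `profile` data.frame from [scanLod()].
#' @param prob credible mass (default 0.95).
#' @return list `chrom`, `cM_lo`, `cM_hi`, `bp_lo`, `bp_hi`, `mass`.
#' @export
bayesInterval <- function(profile, prob = 0.95) {
  peak_row <- which.max(profile$lod)
  ch <- profile$chrom[peak_row]
  sub <- profile[profile$chrom == ch, , drop = FALSE]
  sub <- sub[order(sub$cM), , drop = FALSE]
  w <- 10^sub$lod
  w <- w / sum(w)
  peak <- which.max(sub$lod)
  cs <- cumsum(c(0, w))
  best <- NULL
  for (i in seq_len(peak)) {
    need <- prob + cs[i]
    js <- which(cs[(peak + 1):(nrow(sub) + 1)] >= need - 1e-12)
    if (!length(js)) next
    jj <- peak + js[1] - 1L
    width <- jj - i
    if (is.null(best) || width < best$width)
      best <- list(i = i, j = jj, width = width, mass = cs[jj + 1] - cs[i])
  }
  if (is.null(best)) best <- list(i = 1, j = nrow(sub),
                                  mass = 1, width = nrow(sub) - 1)
  list(chrom = ch, cM_lo = sub$cM[best$i], cM_hi = sub$cM[best$j],
       bp_lo = sub$pos_bp[best$i], bp_hi = sub$pos_bp[best$j],
       mass = best$mass)
}

#' Rank candidate genes in a QTL interval by haplotype divergence
#'
#' Genes inside the credible interval are prioritised by divergence between
#' the primary and alternative haplotypes of the outbred focal genome:
#' genes found only in the alternative assembly (`alt_only`), genes present
#' on both haplotypes with peptide identity below `identity_threshold`
#' percent, and primary-only genes where an alternative contig spans the
#' locus (higher-confidence PAV) are high priority; primary-only genes with
#' no alternative contig likely sit in homozygous regions and are low
#' priority. Optional annotation tags (e.g. LRR/immune domains) are
#' attached as metadata.
#'
#' @param projection output of [projectToAltHaplotype()].
#' @param interval_primary_genes primary gene ids inside the interval.
#' @param interval_alt_genes optional alt-only gene ids inside the
#'   interval.
#' @param identity_threshold peptide identity (%) below which a both-
#'   haplotype pair is prioritised (default 98).
#' @param tags optional named character vector gene id -> tag (e.g.
#'   "LRR").
#' @return data.frame `gene`, `class`, `identity_pct`, `priority`, `tag`,
#'   ordered high priority first.
#' @export
rankCandidates <- function(projection, interval_primary_genes,
                           interval_alt_genes = character(),
                           identity_threshold = 98, tags = NULL) {
  comp <- projection$comparisons
  comp <- comp[comp$primary_gene %in% interval_primary_genes, , drop = FALSE]
  rows <- list()
  if (nrow(comp)) {
    pr <- ifelse(comp$class == "both" & !is.na(comp$identity_pct) &
                   comp$identity_pct < identity_threshold, "high",
          ifelse(comp$class == "primary_only_with_alt_contig", "high", "low"))
    rows[[1]] <- data.frame(gene = comp$primary_gene, class = comp$class,
                            identity_pct = comp$identity_pct, priority = pr,
                            stringsAsFactors = FALSE)
  }
  if (length(interval_alt_genes)) {
    rows[[length(rows) + 1L]] <- data.frame(
      gene = interval_alt_genes, class = "alt_only",
      identity_pct = NA_real_, priority = "high", stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene = character(), class = character(),
                      identity_pct = numeric(), priority = character(),
                      tag = character()))
  out <- do.call(rbind, rows)
  out$tag <- if (is.null(tags)) NA_character_ else unname(tags[out$gene])
  out <- out[order(out$priority != "high", out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
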
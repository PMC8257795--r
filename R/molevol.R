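NTS <- c("A", "C", "G", "T")

.ng86 <- new.env(parent = emptyenv())

# fractional synonymous site count per sense codon (stop-codon targets
# count as non-synonymous so sites per codon always sum to 3)
ng86_syn_sites <- function() {
  if (!is.null(.ng86$syn_sites)) return(.ng86$syn_sites)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  s <- vapply(sense, function(cod) {
    chars <- strsplit(cod, "")[[1]]
    tot <- 0
    for (p in 1:3) {
      for (nt in setdiff(NTS, chars[p])) {
        alt <- chars; alt[p] <- nt
        altc <- paste(alt, collapse = "")
        if (gc[[altc]] != "*" && gc[[altc]] == gc[[cod]]) tot <- tot + 1 / 3
      }
    }
    tot
  }, numeric(1))
  .ng86$syn_sites <- s
  s
}

# synonymous/non-synonymous differences between two sense codons, averaged
# over all minimal mutational pathways; pathways through stop codons are
# excluded (all-blocked pairs fall back to counting stop steps as
# non-synonymous)
ng86_pair_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  key <- paste(c1, c2)
  if (is.null(.ng86$pairs)) .ng86$pairs <- list()
  cached <- .ng86$pairs[[key]]
  if (!is.null(cached)) return(cached)
  gc <- Biostrings::GENETIC_CODE
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  pos <- which(a != b)
  perms <- permutations_of(pos)
  score_path <- function(ord, allow_stops) {
    cur <- a; sd <- 0; nd <- 0
    for (p in ord) {
      nxt <- cur; nxt[p] <- b[p]
      cs <- paste(cur, collapse = ""); ns <- paste(nxt, collapse = "")
      if (gc[[ns]] == "*" && !identical(nxt, b)) {
        if (!allow_stops) return(NULL)
        nd <- nd + 1
      } else if (gc[[ns]] == "*" || gc[[cs]] == "*") {
        if (!allow_stops) return(NULL)
        nd <- nd + 1
      } else if (gc[[cs]] == gc[[ns]]) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  scored <- Filter(Negate(is.null), lapply(perms, score_path, allow_stops = FALSE))
  if (!length(scored))
    scored <- lapply(perms, score_path, allow_stops = TRUE)
  m <- do.call(rbind, scored)
  out <- c(sd = mean(m[, 1]), nd = mean(m[, 2]))
  if (is.null(.ng86$pairs)) .ng86$pairs <- list()
  .ng86$pairs[[key]] <- out
  out
}

permutations_of <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in permutations_of(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

split_codons <- function(seq) {
  seq <- toupper(as.character(seq))
  n <- nchar(seq)
  if (n %% 3 != 0) {
    warning("sequence length not a multiple of 3; trailing ",
            n %% 3, " nt trimmed")
    seq <- substr(seq, 1, n - n %% 3)
  }
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

translate_codons <- function(codons, label = "sequence") {
  gc <- Biostrings::GENETIC_CODE
  aa <- vapply(codons, function(cod) {
    if (cod %in% names(gc)) gc[[cod]] else "X"
  }, character(1), USE.NAMES = FALSE)
  if (length(aa) && aa[length(aa)] == "*") {
    aa <- aa[-length(aa)]
    codons <- codons[-length(codons)]
  }
  stops <- which(aa == "*")
  if (length(stops))
    stop(sprintf("internal stop codon in %s at codon %d", label, stops[1]))
  list(codons = codons, aa = paste(aa, collapse = ""))
}

#' Protein-guided codon alignment of two CDS
#'
#' Translates both coding sequences (trailing partial codons are trimmed
#' with a warning; a terminal stop codon is dropped; internal stops raise
#' an error naming the codon position), aligns the proteins globally
#' (BLOSUM62) and back-translates the alignment to codons. Gap codons are
#' `"---"`.
#'
#' @param cds_a,cds_b coding sequences (character or `DNAString`).
#' @return list with character vectors `codons_a`, `codons_b` of equal
#'   length (aligned codon columns).
#' @export
alignCodons <- function(cds_a, cds_b) {
  ta <- translate_codons(split_codons(cds_a), "cds_a")
  tb <- translate_codons(split_codons(cds_b), "cds_b")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ta$aa), Biostrings::AAString(tb$aa),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ca <- character(length(pa)); cb <- character(length(pb))
  ia <- 0L; ib <- 0L
  for (i in seq_along(pa)) {
    if (pa[i] == "-") ca[i] <- "---" else { ia <- ia + 1L; ca[i] <- ta$codons[ia] }
    if (pb[i] == "-") cb[i] <- "---" else { ib <- ib + 1L; cb[i] <- tb$codons[ib] }
  }
  list(codons_a = ca, codons_b = cb)
}

#' Nei-Gojobori (1986) Ka/Ks from a codon alignment
#'
#' Fractional synonymous/non-synonymous site counting averaged over both
#' sequences, pathway-averaged difference counting for multi-hit codons,
#' and Jukes-Cantor correction d = -(3/4) ln(1 - (4/3) p). Codon columns
#' containing gaps or ambiguous bases are excluded. Proportions >= 3/4 are
#' flagged saturated and the corresponding rate is `NA`.
#'
#' @param aln output of [alignCodons()] (or a list with `codons_a`,
#'   `codons_b`).
#' @return list `Ka`, `Ks`, `N`, `S` (site counts), `Nd`, `Sd` (difference
#'   counts), `n_codons`, `saturated`.
#' @export
kaksNG86 <- function(aln) {
  ca <- aln$codons_a; cb <- aln$codons_b
  ok <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE) &
    grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  gc <- Biostrings::GENETIC_CODE
  ok <- ok & gc[ca] != "*" & gc[cb] != "*"
  ca <- ca[ok]; cb <- cb[ok]
  if (length(ca) < 10) stop("fewer than 10 usable (gap-free) codons")
  ssites <- ng86_syn_sites()
  S <- (sum(ssites[ca]) + sum(ssites[cb])) / 2
  N <- 3 * length(ca) - S
  diffs <- vapply(seq_along(ca), function(i) ng86_pair_diffs(ca[i], cb[i]),
                  numeric(2))
  Sd <- sum(diffs[1, ]); Nd <- sum(diffs[2, ])
  ps <- Sd / S; pn <- Nd / N
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  sat_s <- ps >= 0.75; sat_n <- pn >= 0.75
  list(Ka = if (sat_n) NA_real_ else jc(pn),
       Ks = if (sat_s) NA_real_ else jc(ps),
       N = N, S = S, Nd = Nd, Sd = Sd, n_codons = length(ca),
       saturated = sat_s || sat_n)
}

#' Mean and standard error of the mean
#'
#' SEM = sample standard deviation / sqrt(n). With a single value the SEM
#' is undefined (`NA`).
#'
#' @param values numeric vector (NAs dropped).
#' @return list `mean`, `sem`, `n`.
#' @export
meanSem <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) stop("no values")
  list(mean = mean(values),
       sem = if (n < 2) NA_real_ else stats::sd(values) / sqrt(n),
       n = n)
}

#' Sliding-window quantile transform of per-gene values
#'
#' Each value is replaced by its empirical quantile
#' q = (mid-rank - 0.5) / n within the vector (one chromosome of one
#' genome, ordered by pan position), then a sliding window of `window`
#' genes (step 1) averages the quantiles. Output is bounded in \[0, 1\] and
#' invariant to monotone transforms of the input. A vector shorter than
#' the window emits no windows, with a warning.
#'
#' @param values per-gene values (e.g. Ks), ordered by pan position.
#' @param window window size in genes (default 100).
#' @return data.frame `center` (index of the window centre,
#'   (i + i + window - 1)/2) and `value` (mean quantile).
#' @export
slidingQuantile <- function(values, window = 100) {
  n <- length(values)
  if (n < window) {
    warning("fewer genes (", n, ") than the window (", window, "); no windows")
    return(data.frame(center = numeric(), value = numeric()))
  }
  q <- (rank(values, ties.method = "average") - 0.5) / n
  cs <- cumsum(c(0, q))
  starts <- seq_len(n - window + 1)
  vals <- (cs[starts + window] - cs[starts]) / window
  data.frame(center = starts + (window - 1) / 2, value = vals)
}

#' Sliding quantile track across genomes and chromosomes
#'
#' Applies [slidingQuantile()] within each (genome, chromosome) group of a
#' per-gene table ordered by pan position.
#'
#' @param df data.frame with columns `genome`, `chrom`, `value`, ordered by
#'   pan position within each group.
#' @param window window size in genes.
#' @return data.frame `genome`, `chrom`, `center`, `value`.
#' @export
slidingQuantileTrack <- function(df, window = 100) {
  stopifnot(all(c("genome", "chrom", "value") %in% names(df)))
  parts <- split(df, paste(df$genome, df$chrom, sep = "\r"), drop = TRUE)
  out <- lapply(parts, function(p) {
    w <- withCallingHandlers(slidingQuantile(p$value, window),
                             warning = function(w) invokeRestart("muffleWarning"))
    if (nrow(w) == 0) return(NULL)
    data.frame(genome = p$genome[1], chrom = p$chrom[1], w,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    return(data.frame(genome = character(), chrom = character(),
                      center = numeric(), value = numeric()))
  rownames(out) <- NULL
  out
}
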
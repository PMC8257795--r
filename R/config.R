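#' Collinear-chain parameters
#'
#' Defaults follow the paralog (homeolog) chaining settings: a maximum
#' anchor gap of 50 gene ranks and a minimum of 10 anchors per block, with
#' DBSCAN density refinement at radius 50 and 10 minimum hits. For
#' pan-genome (orthology) runs use [panChainParams()], which tightens the
#' gap to 20 ranks.
#'
#' @param max_gap maximum rank gap between consecutive anchors, both axes.
#' @param min_size minimum anchors per retained block.
#' @param dbscan_radius DBSCAN neighbourhood radius in rank units.
#' @param dbscan_min_hits DBSCAN core-point threshold (neighbours incl. self).
#' @return list of chaining parameters.
#' @export
chainParams <- function(max_gap = 50, min_size = 10,
                        dbscan_radius = 50, dbscan_min_hits = 10) {
  stopifnot(max_gap >= 1, min_size >= 1, dbscan_radius > 0, dbscan_min_hits >= 1)
  list(max_gap = max_gap, min_size = min_size,
       dbscan_radius = dbscan_radius, dbscan_min_hits = dbscan_min_hits)
}

#' @rdname chainParams
#' @export
panChainParams <- function(max_gap = 20, min_size = 10,
                           dbscan_radius = 50, dbscan_min_hits = 10) {
  chainParams(max_gap, min_size, dbscan_radius, dbscan_min_hits)
}

#' Variant pruning configuration for ancestry inference
#'
#' Mirrors the SNP pruning used before local-ancestry decoding: biallelic
#' sites with a minor allele count of at least 3, no missing data, and
#' pairwise linkage disequilibrium r^2 at most 0.999 within trailing
#' 100-SNP windows.
#'
#' @param min_minor_allele_count minimum minor allele count.
#' @param allow_missing keep sites with missing calls (default FALSE).
#' @param max_r2 maximum LD r^2; the later site of an offending pair is
#'   dropped.
#' @param window trailing window size in SNPs for LD checks.
#' @return list of pruning parameters.
#' @export
pruneConfig <- function(min_minor_allele_count = 3, allow_missing = FALSE,
                        max_r2 = 0.999, window = 100) {
  stopifnot(min_minor_allele_count >= 0, max_r2 > 0, window >= 2)
  list(min_minor_allele_count = min_minor_allele_count,
       allow_missing = allow_missing, max_r2 = max_r2, window = window)
}

#' Local-ancestry HMM configuration
#'
#' A one-parameter switch-rate Markov model over diploid ancestry states
#' (unordered pairs of sources). Each haplotype switches ancestry along the
#' genetic map as a Poisson process with rate `switch_rate` per morgan; a
#' switching haplotype draws its new ancestry from `ancestry_priors`.
#' Genotype emissions mix the source allele frequencies with a symmetric
#' per-allele genotyping error `genotyping_error` (the cited analysis used
#' e = 1e-3).
#'
#' @param n_sources number of source populations.
#' @param switch_rate expected ancestry switches per morgan per haplotype.
#' @param ancestry_priors per-source prior proportions (sum to 1); e.g. the
#'   global ancestry estimates.
#' @param genotyping_error per-allele misread probability in \[0, 0.5).
#' @return list of HMM parameters.
#' @export
hmmConfig <- function(n_sources = 4, switch_rate = 1,
                      ancestry_priors = rep(1 / n_sources, n_sources),
                      genotyping_error = 1e-3) {
  stopifnot(n_sources >= 2, switch_rate >= 0,
            length(ancestry_priors) == n_sources,
            abs(sum(ancestry_priors) - 1) < 1e-8,
            genotyping_error >= 0, genotyping_error < 0.5)
  list(n_sources = n_sources, switch_rate = switch_rate,
       ancestry_priors = ancestry_priors, genotyping_error = genotyping_error)
}

#' Pseudo-testcross marker filter configuration
#'
#' Thresholds applied before linkage analysis: sites with minor allele
#' frequency < 0.05, heterozygous call frequency > 0.8, missing call
#' frequency > 0.1 or more than two alleles are removed, followed by
#' trimming the 1% of loci with the most extreme mean read depths.
#'
#' @param min_maf minimum minor allele frequency (strict: MAF < min_maf drops).
#' @param max_het_freq maximum heterozygous call frequency (strict).
#' @param max_missing maximum missing call frequency (strict).
#' @param max_alleles maximum distinct alleles per site.
#' @param depth_trim_fraction fraction trimmed from each depth tail.
#' @return list of filter parameters.
#' @export
markerFilterConfig <- function(min_maf = 0.05, max_het_freq = 0.8,
                               max_missing = 0.1, max_alleles = 2,
                               depth_trim_fraction = 0.01) {
  stopifnot(min_maf >= 0, min_maf <= 0.5, max_het_freq > 0, max_missing >= 0,
            max_alleles >= 2, depth_trim_fraction >= 0, depth_trim_fraction < 0.5)
  list(min_maf = min_maf, max_het_freq = max_het_freq,
       max_missing = max_missing, max_alleles = max_alleles,
       depth_trim_fraction = depth_trim_fraction)
}

#' QTL scan configuration
#'
#' @param step pseudomarker step in cM.
#' @param map_function map function for cM/recombination conversions
#'   (only "kosambi" is implemented).
#' @param error_prob genotyping error probability used by map estimation
#'   and genotype-probability interpolation.
#' @param n_permutations permutations for the genome-wide threshold
#'   (the published analysis used 10,000; tests use 1,000).
#' @param kinship kinship scheme; "loco" (leave one chromosome out) or
#'   "none".
#' @param bayes_prob Bayes credible interval coverage.
#' @param seed optional integer seed for the permutation draw.
#' @return list of scan parameters.
#' @export
scanConfig <- function(step = 0.1, map_function = "kosambi",
                       error_prob = 0.0165, n_permutations = 10000,
                       kinship = c("loco", "none"), bayes_prob = 0.95,
                       seed = NULL) {
  kinship <- match.arg(kinship)
  stopifnot(step > 0, error_prob >= 0, error_prob < 0.5,
            bayes_prob > 0, bayes_prob < 1)
  if (!identical(map_function, "kosambi"))
    stop("only the Kosambi map function is implemented")
  list(step = step, map_function = map_function, error_prob = error_prob,
       n_permutations = n_permutations, kinship = kinship,
       bayes_prob = bayes_prob, seed = seed)
}
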
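#' @import methods
#' @importFrom stats setNames
NULL

#' GenotypeMatrix: diploid genotypes as reference-allele counts
#'
#' Container for a sample-by-site genotype matrix coded as reference-allele
#' counts (0, 1, 2; `NA` = missing), the convention used throughout the
#' local-ancestry and QTL machinery. Sites carry 1-based physical positions
#' as in VCF; multiallelic records are flagged for downstream removal rather
#' than dropped at parse time.
#'
#' @slot samples character vector of sample identifiers (rows of `calls`).
#' @slot sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, and logical `multiallelic`.
#' @slot calls integer matrix, samples x sites, values in `c(0:2, NA)`.
#' @slot depth `NULL` or a numeric matrix of read depths, same shape as
#'   `calls`.
#'
#' @export
setClass("GenotypeMatrix",
  representation(
    samples = "character",
    sites = "data.frame",
    calls = "matrix",
    depth = "ANY"
  )
)

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  if (nrow(object@calls) != length(object@samples))
    msg <- c(msg, "nrow(calls) must equal length(samples)")
  if (ncol(object@calls) != nrow(object@sites))
    msg <- c(msg, "ncol(calls) must equal nrow(sites)")
  need <- c("chrom", "pos", "ref", "alt", "multiallelic")
  if (!all(need %in% names(object@sites)))
    msg <- c(msg, paste("sites must have columns:", paste(need, collapse = ", ")))
  bad <- object@calls[!is.na(object@calls)]
  if (length(bad) && (any(bad < 0) || any(bad > 2)))
    msg <- c(msg, "calls must be reference-allele counts in 0..2 or NA")
  if (!is.null(object@depth) &&
      !identical(dim(object@depth), dim(object@calls)))
    msg <- c(msg, "depth must be NULL or match dim(calls)")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeMatrix
#'
#' @param samples character sample ids.
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt`,
#'   `multiallelic` columns.
#' @param calls samples x sites matrix of reference-allele counts.
#' @param depth optional read-depth matrix.
#' @return A [GenotypeMatrix-class] object.
#' @export
GenotypeMatrix <- function(samples, sites, calls, depth = NULL) {
  storage.mode(calls) <- "integer"
  if (!"multiallelic" %in% names(sites)) sites$multiallelic <- FALSE
  new("GenotypeMatrix", samples = as.character(samples), sites = sites,
      calls = calls, depth = depth)
}

#' @describeIn GenotypeMatrix-class sample identifiers
#' @param x,object a `GenotypeMatrix`
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) x@samples)

#' @describeIn GenotypeMatrix-class site table (chrom, pos, ref, alt, multiallelic)
#' @export
setGeneric("siteInfo", function(x) standardGeneric("siteInfo"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("siteInfo", "GenotypeMatrix", function(x) x@sites)

#' @describeIn GenotypeMatrix-class reference-allele count matrix
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("genotypeCalls", "GenotypeMatrix", function(x) x@calls)

#' @describeIn GenotypeMatrix-class read-depth matrix or NULL
#' @export
setGeneric("readDepth", function(x) standardGeneric("readDepth"))

#' @rdname GenotypeMatrix-class
#' @export
setMethod("readDepth", "GenotypeMatrix", function(x) x@depth)

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", length(object@samples), "samples x",
      nrow(object@sites), "sites\n")
  cat("  multiallelic sites:", sum(object@sites$multiallelic), "\n")
  cat("  missing calls:", sum(is.na(object@calls)), "\n")
})

#' Pangenome: an ordered, synteny-anchored orthogroup table
#'
#' Each row (entry) is one orthogroup placed on the reference genome's
#' gene-rank coordinate system. Presence/absence, per-genome member lists
#' (tandem arrays condensed) and one representative gene per genome are
#' carried along. Entries are totally ordered by
#' (`pan_chrom`, `pan_position`, `pan_id`); orthogroups with no syntenic
#' anchor sit in the `"unplaced"` pseudo-chromosome.
#'
#' @slot entries data.frame with columns `pan_id`, `pan_chrom`,
#'   `pan_position`.
#' @slot genomes character vector of genome labels (columns of `presence`).
#' @slot presence logical matrix, entries x genomes.
#' @slot members list (per genome) of lists (per entry) of gene ids.
#' @slot representative character matrix, entries x genomes (NA if absent).
#' @slot reference the reference genome label.
#' @slot outgroup optional outgroup genome label excluded from PAV
#'   summaries (`NA_character_` if none).
#'
#' @export
setClass("Pangenome",
  representation(
    entries = "data.frame",
    genomes = "character",
    presence = "matrix",
    members = "list",
    representative = "matrix",
    reference = "character",
    outgroup = "character"
  )
)

setValidity("Pangenome", function(object) {
  msg <- character()
  n <- nrow(object@entries)
  if (!all(c("pan_id", "pan_chrom", "pan_position") %in% names(object@entries)))
    msg <- c(msg, "entries needs pan_id, pan_chrom, pan_position")
  if (nrow(object@presence) != n || ncol(object@presence) != length(object@genomes))
    msg <- c(msg, "presence must be entries x genomes")
  if (!identical(dim(object@representative), dim(object@presence)))
    msg <- c(msg, "representative must match presence dimensions")
  if (!object@reference %in% object@genomes)
    msg <- c(msg, "reference must be one of the genomes")
  for (g in object@genomes) {
    memb <- object@members[[g]]
    if (is.null(memb) || length(memb) != n) {
      msg <- c(msg, sprintf("members[['%s']] must have one element per entry", g))
      next
    }
    has <- vapply(memb, function(m) length(m) > 0L, logical(1))
    if (!identical(unname(has), unname(object@presence[, g])))
      msg <- c(msg, sprintf("presence[, '%s'] must mirror non-empty members", g))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "Pangenome", function(object) {
  cat("Pangenome:", nrow(object@entries), "orthogroup entries across",
      length(object@genomes), "genomes\n")
  cat("  reference:", object@reference,
      if (!is.na(object@outgroup)) paste0("(outgroup: ", object@outgroup, ")"),
      "\n")
  cat("  chromosomes:", length(unique(object@entries$pan_chrom)), "\n")
  cat("  unplaced entries:", sum(object@entries$pan_chrom == "unplaced"), "\n")
})

#' @describeIn Pangenome-class ordered entry table
#' @param x,object a `Pangenome`
#' @export
setGeneric("panEntries", function(x) standardGeneric("panEntries"))

#' @rdname Pangenome-class
#' @export
setMethod("panEntries", "Pangenome", function(x) x@entries)

#' @describeIn Pangenome-class logical presence matrix (entries x genomes)
#' @export
setGeneric("panPresence", function(x) standardGeneric("panPresence"))

#' @rdname Pangenome-class
#' @export
setMethod("panPresence", "Pangenome", function(x) x@presence)

#' @describeIn Pangenome-class genome labels
#' @export
setGeneric("panGenomes", function(x) standardGeneric("panGenomes"))

#' @rdname Pangenome-class
#' @export
setMethod("panGenomes", "Pangenome", function(x) x@genomes)

#' AncestryPosterior: per-marker posterior over diploid ancestry states
#'
#' Posterior probabilities from the local-ancestry hidden Markov model.
#' States are the unordered pairs of source populations (10 states for 4
#' sources), labelled `"i/j"` with `i <= j` (source indices or names).
#'
#' @slot prob numeric matrix, markers x states; rows sum to 1.
#' @slot states character state labels.
#' @slot positions numeric physical positions (bp), one per marker.
#' @slot chrom chromosome label.
#' @slot priors stationary prior probability of each state.
#'
#' @export
setClass("AncestryPosterior",
  representation(
    prob = "matrix",
    states = "character",
    positions = "numeric",
    chrom = "character",
    priors = "numeric"
  )
)

setValidity("AncestryPosterior", function(object) {
  msg <- character()
  if (ncol(object@prob) != length(object@states))
    msg <- c(msg, "ncol(prob) must equal length(states)")
  if (nrow(object@prob) != length(object@positions))
    msg <- c(msg, "nrow(prob) must equal length(positions)")
  if (length(object@priors) != length(object@states))
    msg <- c(msg, "priors must have one value per state")
  rs <- rowSums(object@prob)
  if (length(rs) && any(abs(rs - 1) > 1e-9))
    msg <- c(msg, "posterior rows must sum to 1 (tol 1e-9)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AncestryPosterior", function(object) {
  cat("AncestryPosterior:", nrow(object@prob), "markers,",
      length(object@states), "diploid ancestry states\n")
  cat("  chrom:", object@chrom, " span:",
      if (length(object@positions)) paste0(min(object@positions), "-",
                                           max(object@positions)) else "-", "bp\n")
})

#' @describeIn AncestryPosterior-class posterior probability matrix
#' @param x,object an `AncestryPosterior`
#' @export
setGeneric("posteriorProb", function(x) standardGeneric("posteriorProb"))

#' @rdname AncestryPosterior-class
#' @export
setMethod("posteriorProb", "AncestryPosterior", function(x) x@prob)

#' @describeIn AncestryPosterior-class state labels ("i/j", i <= j)
#' @export
setGeneric("ancestryStates", function(x) standardGeneric("ancestryStates"))

#' @rdname AncestryPosterior-class
#' @export
setMethod("ancestryStates", "AncestryPosterior", function(x) x@states)

#' CrossGenotypes: phase-coded pseudo-testcross genotypes
#'
#' Progeny-by-marker matrix coded by which haplotype of the heterozygous
#' (focal) parent was inherited: 1 = phase-1 haplotype ("A"), 0 = phase-2
#' ("B"), `NA` = missing. Markers carry physical (bp) and genetic (cM)
#' positions plus a parent-of-origin phase label.
#'
#' @slot geno integer matrix, progeny x markers, values 0/1/NA.
#' @slot markers data.frame with columns `marker`, `chrom`, `pos_bp`,
#'   `cM` (NA until a map is estimated), `phase` (e.g. "Mahan-like").
#' @slot progeny character progeny identifiers.
#'
#' @export
setClass("CrossGenotypes",
  representation(
    geno = "matrix",
    markers = "data.frame",
    progeny = "character"
  )
)

setValidity("CrossGenotypes", function(object) {
  msg <- character()
  if (nrow(object@geno) != length(object@progeny))
    msg <- c(msg, "nrow(geno) must equal length(progeny)")
  if (ncol(object@geno) != nrow(object@markers))
    msg <- c(msg, "ncol(geno) must equal nrow(markers)")
  need <- c("marker", "chrom", "pos_bp", "cM", "phase")
  if (!all(need %in% names(object@markers)))
    msg <- c(msg, paste("markers must have columns:", paste(need, collapse = ", ")))
  v <- object@geno[!is.na(object@geno)]
  if (length(v) && !all(v %in% c(0L, 1L)))
    msg <- c(msg, "geno must be 0/1/NA (phase-coded)")
  if (length(msg)) msg else TRUE
})

#' Construct a CrossGenotypes object
#'
#' @param geno progeny x marker 0/1/NA matrix (1 = phase-1 haplotype).
#' @param markers data.frame with `marker`, `chrom`, `pos_bp`, `cM`, `phase`.
#' @param progeny character progeny ids.
#' @return A [CrossGenotypes-class] object.
#' @export
CrossGenotypes <- function(geno, markers, progeny) {
  storage.mode(geno) <- "integer"
  if (!"cM" %in% names(markers)) markers$cM <- NA_real_
  if (!"phase" %in% names(markers)) markers$phase <- NA_character_
  new("CrossGenotypes", geno = geno, markers = markers,
      progeny = as.character(progeny))
}

setMethod("show", "CrossGenotypes", function(object) {
  cat("CrossGenotypes:", length(object@progeny), "progeny x",
      nrow(object@markers), "markers on",
      length(unique(object@markers$chrom)), "chromosomes\n")
  if (!all(is.na(object@markers$cM)))
    cat("  map length:",
        round(sum(tapply(object@markers$cM, object@markers$chrom, max,
                         na.rm = TRUE)), 1), "cM\n")
})

#' @describeIn CrossGenotypes-class marker table
#' @param x,object a `CrossGenotypes`
#' @export
setGeneric("markerInfo", function(x) standardGeneric("markerInfo"))

#' @rdname CrossGenotypes-class
#' @export
setMethod("markerInfo", "CrossGenotypes", function(x) x@markers)

#' @describeIn CrossGenotypes-class phase-coded genotype matrix
#' @export
setGeneric("crossGeno", function(x) standardGeneric("crossGeno"))

#' @rdname CrossGenotypes-class
#' @export
setMethod("crossGeno", "CrossGenotypes", function(x) x@geno)
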
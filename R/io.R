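#' Parse a GFF3 gene annotation into a gene-model table
#'
#' Reads the `gene` features of a GFF3 file and returns one row per gene
#' with coordinates converted from the GFF3 1-based inclusive convention to
#' the internal 0-based half-open convention. Gene-rank-order positions
#' (`rank`) are assigned per chromosome by ascending start, ties broken by
#' gene id (lexicographic), and are the coordinate system used by all
#' synteny operations.
#'
#' @param gff3_path path to a GFF3 file.
#' @param genome_label label attached to every gene (the genome name).
#' @return data.frame with columns `gene_id`, `genome`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `rank` (0-based within
#'   chromosome), `length`.
#' @export
parseAnnotation <- function(gff3_path, genome_label) {
  stopifnot(is.character(gff3_path), file.exists(gff3_path))
  # light pre-scan so malformed records are reported with their line number
  raw <- readLines(gff3_path)
  body <- which(!grepl("^#", raw) & nzchar(raw))
  for (i in body) {
    f <- strsplit(raw[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) next
    if (tolower(f[3]) != "gene") next
    s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e) || e < s)
      stop(sprintf("parse error at line %d: end < start (or non-numeric coordinates)", i))
    if (!grepl("(^|;)ID=", f[9]))
      stop(sprintf("parse error at line %d: gene feature lacks an ID attribute", i))
  }
  gr <- rtracklayer::import(gff3_path)
  gr <- gr[tolower(as.character(gr$type)) == "gene"]
  if (length(gr) == 0)
    return(data.frame(gene_id = character(), genome = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), rank = integer(), length = integer()))
  ids <- as.character(gr$ID)
  if (anyDuplicated(ids))
    stop("parse error: duplicate gene IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  df <- data.frame(
    gene_id = ids,
    genome = genome_label,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  df$length <- df$end - df$start
  assignGeneRanks(df)
}

#' Assign per-chromosome gene rank order
#'
#' Ranks are 0-based, contiguous within each chromosome, ordered by
#' ascending start with ties broken by gene id. Strand is ignored.
#'
#' @param genes gene-model data.frame (needs `chrom`, `start`, `gene_id`).
#' @return the same data.frame, reordered, with a `rank` column.
#' @export
assignGeneRanks <- function(genes) {
  ord <- order(genes$chrom, genes$start, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  genes$rank <- as.integer(stats::ave(seq_len(nrow(genes)), genes$chrom,
                                      FUN = seq_along)) - 1L
  rownames(genes) <- NULL
  genes
}

#' Write a gene-model table as GFF3
#'
#' Inverse of [parseAnnotation()]: internal 0-based half-open coordinates
#' are converted back to GFF3 1-based inclusive.
#'
#' @param genes gene-model data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeAnnotationGff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand
  )
  gr$type <- "gene"
  gr$ID <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Parse a VCF into a GenotypeMatrix
#'
#' GT fields are converted to reference-allele counts: each "0" allele
#' contributes one count, so `0/0 -> 2`, `0/1 -> 1`, `1/1 -> 0`, `./.` ->
#' missing. Records with more than one ALT allele are kept but flagged
#' `multiallelic` for downstream removal. The DP FORMAT field is captured
#' as the depth matrix when present.
#'
#' @param vcf_path path to an (optionally gzipped) VCF.
#' @return A [GenotypeMatrix-class] object.
#' @export
parseGenotypes <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- as.character(fix[, "ALT"])
  sites <- data.frame(
    chrom = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = as.character(fix[, "REF"]),
    alt = alt,
    multiallelic = grepl(",", alt, fixed = TRUE),
    stringsAsFactors = FALSE
  )
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  calls <- apply(gt, 2, function(col) {
    vapply(seq_along(col), function(i) {
      g <- col[i]
      if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
      alleles <- strsplit(g, "[/|]")[[1]]
      if (any(alleles == ".")) return(NA_integer_)
      if (!all(grepl("^[0-9]+$", alleles)))
        stop(sprintf("malformed GT '%s' at %s:%d", g, sites$chrom[i], sites$pos[i]))
      sum(alleles == "0")
    }, integer(1))
  })
  calls <- t(matrix(calls, nrow = nrow(sites), ncol = length(samples),
                    dimnames = list(NULL, samples)))
  depth <- NULL
  if ("DP" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    if (!is.null(dp)) depth <- t(dp)
  }
  GenotypeMatrix(samples = samples, sites = sites, calls = calls, depth = depth)
}

#' Write a GenotypeMatrix as an uncompressed VCF
#'
#' Emits a minimal VCFv4.2 with GT (and DP when depths are present).
#' Reference-allele counts are mapped back to unphased genotypes
#' (`2 -> 0/0`, `1 -> 0/1`, `0 -> 1/1`, missing -> `./.`); multiallelic
#' flags are preserved through the ALT column.
#'
#' @param gm a [GenotypeMatrix-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypesVcf <- function(gm, path) {
  sites <- siteInfo(gm)
  calls <- genotypeCalls(gm)
  has_dp <- !is.null(readDepth(gm))
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (has_dp)
    hdr <- c(hdr, "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", sampleIds(gm)), collapse = "\t"))
  gt_map <- c("1/1", "0/1", "0/0")  # indexed by count + 1
  rows <- vapply(seq_len(nrow(sites)), function(j) {
    g <- calls[, j]
    gt <- ifelse(is.na(g), "./.", gt_map[g + 1L])
    if (has_dp) {
      dp <- readDepth(gm)[, j]
      gt <- paste(gt, ifelse(is.na(dp), ".", dp), sep = ":")
    }
    paste(c(sites$chrom[j], sites$pos[j], ".", sites$ref[j], sites$alt[j],
            ".", "PASS", ".", if (has_dp) "GT:DP" else "GT", gt),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Assembly summary: alternative-haplotype fraction
#'
#' The fraction of the primary assembly represented in the alternative
#' haplotype assembly, reported to one decimal as a percentage (e.g. a
#' 674.27 Mb primary with a 603.2 Mb alternative gives 89.5%).
#'
#' @param primary_size_mb primary assembly size, Mb (> 0).
#' @param alt_size_mb alternative haplotype assembly size, Mb (>= 0).
#' @return list with `primary_size_mb`, `alt_size_mb`, `alt_fraction_pct`
#'   (rounded to one decimal).
#' @export
assemblySummary <- function(primary_size_mb, alt_size_mb) {
  if (!is.numeric(primary_size_mb) || primary_size_mb <= 0)
    stop("primary_size_mb must be > 0")
  if (!is.numeric(alt_size_mb) || alt_size_mb < 0)
    stop("alt_size_mb must be >= 0")
  list(primary_size_mb = primary_size_mb,
       alt_size_mb = alt_size_mb,
       alt_fraction_pct = round(100 * alt_size_mb / primary_size_mb, 1))
}
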
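#' @importFrom stats p.adjust pnorm pt pchisq phyper dbinom rbinom rpois
#'   rmultinom runif setNames var complete.cases
#' @importFrom utils read.delim write.table combn head
NULL

TREATMENTS <- c("weak_demography", "strong_demography", "ancestor")
BASES <- c("A", "C", "G", "T")

#' Construct a validated sample sheet
#'
#' A sample sheet describes the identity of each pooled sequencing library:
#' which evolutionary replicate it came from, the demographic treatment, the
#' sampling day (days since the start of the experiment) and the sequencing
#' batch. Ancestor libraries carry treatment `"ancestor"` and may have a
#' missing day.
#'
#' @param df data.frame with columns `sample_id`, `replicate_id`, `treatment`,
#'   `day`, `batch_id`.
#' @return The validated data.frame with class `"sample_sheet"` prepended.
#' @export
sample_sheet <- function(df) {
  req <- c("sample_id", "replicate_id", "treatment", "day", "batch_id")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  df <- df[, req, drop = FALSE]
  df$sample_id <- as.character(df$sample_id)
  df$replicate_id <- as.character(df$replicate_id)
  df$treatment <- as.character(df$treatment)
  df$batch_id <- as.character(df$batch_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- !df$treatment %in% TREATMENTS
  if (any(bad))
    stop("unknown treatment value(s): ", paste(unique(df$treatment[bad]), collapse = ", "))
  day <- suppressWarnings(as.numeric(df$day))
  if (any(!is.na(df$day) & df$day != "" & is.na(day)))
    stop("non-numeric day value in sample sheet")
  df$day <- day
  evolved <- df$treatment != "ancestor"
  if (any(evolved & is.na(df$day)))
    stop("day must be present for every non-ancestor sample")
  if (any(!is.na(df$day) & df$day < 0)) stop("day must be non-negative")
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read a sample sheet from TSV
#'
#' @param path TSV file with header columns `sample_id`, `replicate_id`,
#'   `treatment`, `day`, `batch_id`.
#' @return A [sample_sheet()] (empty if the file has a header only).
#' @export
read_sample_sheet <- function(path) {
  df <- read.delim(path, colClasses = "character", check.names = FALSE)
  sample_sheet(df)
}

#' Write a sample sheet to TSV
#' @param samples a [sample_sheet()]
#' @param path output path
#' @export
write_sample_sheet <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a variant table
#'
#' The central container of the package: a sites-by-samples grid of pooled
#' read counts. Rows are biallelic SNP sites (two alternative bases at one
#' position are two distinct sites); columns are pooled libraries. Allele
#' frequencies are *derived* quantities: `alt/(ref+alt)` where the total
#' depth reaches `min_depth`, and `NA` (missing) otherwise — "no data" is
#' never conflated with "allele absent".
#'
#' @param sites data.frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt` (single bases, `alt != ref`), `qual` (non-negative caller quality).
#' @param samples a [sample_sheet()]
#' @param ref_count,alt_count integer matrices, `nrow(sites)` x `nrow(samples)`.
#' @param min_depth minimum total depth for an allele-frequency estimate
#'   (default 10).
#' @return An object of class `"variant_table"`.
#' @export
variant_table <- function(sites, samples, ref_count, alt_count, min_depth = 10) {
  samples <- sample_sheet(as.data.frame(samples))
  req <- c("contig", "pos", "ref", "alt", "qual")
  miss <- setdiff(req, names(sites))
  if (length(miss)) stop("sites missing columns: ", paste(miss, collapse = ", "))
  sites <- as.data.frame(sites)[, req, drop = FALSE]
  rownames(sites) <- NULL
  sites$contig <- as.character(sites$contig)
  sites$pos <- as.integer(sites$pos)
  sites$ref <- toupper(as.character(sites$ref))
  sites$alt <- toupper(as.character(sites$alt))
  sites$qual <- as.numeric(sites$qual)
  if (nrow(sites)) {
    if (!all(sites$ref %in% BASES) || !all(sites$alt %in% BASES))
      stop("ref/alt must be single bases A, C, G or T")
    if (any(sites$ref == sites$alt)) stop("alt base must differ from ref base")
    if (any(sites$pos < 1)) stop("positions are 1-based; pos must be >= 1")
    if (any(is.na(sites$qual) | sites$qual < 0)) stop("qual must be non-negative")
    key <- site_key(sites)
    if (anyDuplicated(key))
      stop("duplicate (contig, pos, alt) site: ", key[duplicated(key)][1])
  }
  ref_count <- as.matrix(ref_count)
  alt_count <- as.matrix(alt_count)
  if (!all(dim(ref_count) == c(nrow(sites), nrow(samples))) ||
      !all(dim(alt_count) == c(nrow(sites), nrow(samples))))
    stop("count matrices must be nrow(sites) x nrow(samples)")
  storage.mode(ref_count) <- "integer"
  storage.mode(alt_count) <- "integer"
  if (any(ref_count < 0, na.rm = TRUE) || any(alt_count < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  dimnames(ref_count) <- dimnames(alt_count) <-
    list(site_key(sites), samples$sample_id)
  structure(
    list(sites = sites, samples = samples,
         ref_count = ref_count, alt_count = alt_count,
         min_depth = as.integer(min_depth)),
    class = "variant_table"
  )
}

site_key <- function(sites) {
  if (inherits(sites, "variant_table")) sites <- sites$sites
  paste(sites$contig, sites$pos, sites$ref, sites$alt, sep = ":")
}

#' Number of sites / samples in a variant table
#' @param table a [variant_table()]
#' @export
n_sites <- function(table) nrow(table$sites)

#' @rdname n_sites
#' @export
n_samples <- function(table) nrow(table$samples)

#' Sequencing depth per (site, sample)
#' @param table a [variant_table()]
#' @return integer matrix `ref_count + alt_count`
#' @export
depth <- function(table) table$ref_count + table$alt_count

#' Derived allele frequencies with missingness
#'
#' @param table a [variant_table()]
#' @param min_depth override the table's minimum depth for a frequency
#'   estimate; entries with lower total depth are `NA`.
#' @return numeric matrix in `[0, 1]` with `NA` for missing estimates.
#' @export
allele_freq <- function(table, min_depth = table$min_depth) {
  dp <- depth(table)
  af <- table$alt_count / dp
  af[dp < min_depth] <- NA_real_
  af
}

#' Per-site fraction of samples with a missing frequency estimate
#' @param table a [variant_table()]
#' @export
missing_fraction <- function(table) {
  rowMeans(is.na(allele_freq(table)))
}

#' Subset a variant table by site or sample
#'
#' @param table a [variant_table()]
#' @param idx logical or integer index over sites (`subset_sites`) or samples
#'   (`subset_samples`).
#' @export
subset_sites <- function(table, idx) {
  variant_table(table$sites[idx, , drop = FALSE], table$samples,
                table$ref_count[idx, , drop = FALSE],
                table$alt_count[idx, , drop = FALSE],
                min_depth = table$min_depth)
}

#' @rdname subset_sites
#' @export
subset_samples <- function(table, idx) {
  variant_table(table$sites, table$samples[idx, , drop = FALSE],
                table$ref_count[, idx, drop = FALSE],
                table$alt_count[, idx, drop = FALSE],
                min_depth = table$min_depth)
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d site(s) x %d sample(s), min_depth = %d\n",
              n_sites(x), n_samples(x), x$min_depth))
  if (n_sites(x)) {
    af <- allele_freq(x)
    cat(sprintf("  missing allele-frequency estimates: %.1f%%\n",
                100 * mean(is.na(af))))
  }
  invisible(x)
}

#' Construct an ORF record
#'
#' An open reading frame as a strand-aware, possibly multi-segment interval.
#' Coordinates are 1-based inclusive. Coding length is the sum of segment
#' lengths; ORFs whose length is not a multiple of 3 are kept (they still
#' take part in the enrichment scan) but flagged unusable for codon-level
#' effect classification.
#'
#' @param name gene name. In the PBCV-1 convention a trailing `R`/`L` encodes
#'   the transcription direction (R = rightward `+`, L = leftward `-`).
#' @param segments two-column matrix of (start, end) pairs, 1-based inclusive,
#'   sorted and non-overlapping.
#' @param strand `"+"` or `"-"`.
#' @return list of class `"orf"` with fields `name`, `segments`, `strand`,
#'   `length`, `cds_ok`.
#' @export
orf <- function(name, segments, strand) {
  segments <- matrix(as.integer(segments), ncol = 2,
                     dimnames = list(NULL, c("start", "end")))
  o <- order(segments[, 1])
  segments <- segments[o, , drop = FALSE]
  if (any(segments[, 2] < segments[, 1])) stop("ORF segment with end < start: ", name)
  if (nrow(segments) > 1 &&
      any(segments[-1, 1] <= segments[-nrow(segments), 2]))
    stop("overlapping segments within ORF: ", name)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-': ", name)
  len <- sum(segments[, 2] - segments[, 1] + 1L)
  if (len <= 0) stop("ORF with non-positive length: ", name)
  cds_ok <- len %% 3L == 0L
  if (!cds_ok)
    warning("ORF length not a multiple of 3; excluded from codon classification: ",
            name, call. = FALSE)
  structure(list(name = as.character(name), segments = segments,
                 strand = strand, length = len, cds_ok = cds_ok),
            class = "orf")
}

#' Construct a genome annotation
#'
#' @param contig contig name.
#' @param genome_length total contig length in bp.
#' @param orfs list of [orf()] records, all within `[1, genome_length]`.
#' @param sequence optional reference sequence (single string of
#'   length `genome_length`, A/C/G/T).
#' @return list of class `"genome_annotation"`.
#' @export
genome_annotation <- function(contig, genome_length, orfs = list(), sequence = NULL) {
  genome_length <- as.integer(genome_length)
  if (is.na(genome_length) || genome_length < 1) stop("invalid genome_length")
  for (o in orfs) {
    if (!inherits(o, "orf")) stop("orfs must be a list of orf() records")
    if (any(o$segments < 1L) || any(o$segments > genome_length))
      stop("ORF segment outside [1, genome_length]: ", o$name)
  }
  nm <- vapply(orfs, `[[`, "", "name")
  names(orfs) <- nm
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) != genome_length)
      stop("sequence length (", nchar(sequence),
           ") does not match genome_length (", genome_length, ")")
  }
  structure(list(contig = as.character(contig), genome_length = genome_length,
                 orfs = orfs, sequence = sequence),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %s, %d bp, %d ORF(s)%s\n", x$contig,
              x$genome_length, length(x$orfs),
              if (is.null(x$sequence)) "" else ", with sequence"))
  invisible(x)
}
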
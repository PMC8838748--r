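EFFECT_CLASSES <- c("intergenic", "synonymous", "nonsynonymous",
                    "start_lost", "stop_gained", "stop_lost")
# severity used to resolve SNPs covered by several ORFs
EFFECT_SEVERITY <- c(intergenic = 0, synonymous = 1, nonsynonymous = 2,
                     start_lost = 3, stop_gained = 3, stop_lost = 3)
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Classify SNPs into phenotypic-effect classes
#'
#' A codon-level reimplementation of the usual variant-effect annotation
#' for a compact, intron-free viral genome, using the standard genetic
#' code. For every ORF covering a position, the position is mapped to its
#' coding coordinate through the ORF's segments (reverse-complemented on
#' the minus strand), the affected codon is mutated and the amino acids
#' compared: same amino acid is `synonymous`; different, `nonsynonymous`;
#' a non-stop codon turning into a stop is `stop_gained`; a stop losing
#' its stop status is `stop_lost`; any change destroying the ATG of codon
#' one is `start_lost` (a codon-one change that creates a stop is reported
#' as `stop_gained`). Sites covered by no ORF are `intergenic`. When ORFs
#' overlap, the most severe class wins
#' (`start/stop changes > nonsynonymous > synonymous`), with ties broken
#' deterministically by the lowest ORF start. ORFs whose length is not a
#' multiple of 3 are skipped.
#'
#' @param sites data.frame with columns `pos` and `alt` (and optionally
#'   `ref`, which is checked against the reference sequence).
#' @param genome a [genome_annotation()] carrying a sequence.
#' @return character vector of effect classes, one per site.
#' @export
classify_variants <- function(sites, genome) {
  if (is.null(genome$sequence)) stop("genome annotation carries no sequence")
  seqc <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  pos <- as.integer(sites$pos)
  alt <- toupper(as.character(sites$alt))
  if (any(pos < 1 | pos > genome$genome_length))
    stop("site position outside [1, genome_length]")
  if (!all(alt %in% BASES)) stop("alt bases must be A, C, G or T")
  if (!is.null(sites$ref)) {
    ref <- toupper(as.character(sites$ref))
    bad <- which(ref != seqc[pos])
    if (length(bad))
      stop("ref base mismatch with reference sequence at pos ",
           paste(pos[bad[seq_len(min(5, length(bad)))]], collapse = ", "))
  }
  if (any(alt == seqc[pos])) stop("alt base equals the reference base")

  class <- rep("intergenic", length(pos))
  severity <- rep(-1, length(pos))   # any ORF hit outranks intergenic
  tie_start <- rep(Inf, length(pos))
  for (o in genome$orfs) {
    if (!o$cds_ok) next
    gpos <- unlist(lapply(seq_len(nrow(o$segments)),
                          function(k) o$segments[k, 1]:o$segments[k, 2]))
    hit <- which(pos %in% gpos)
    if (!length(hit)) next
    n <- length(gpos)
    idx <- match(pos[hit], gpos)
    cds_i <- if (o$strand == "+") idx else n - idx + 1L
    codon_i <- (cds_i - 1L) %/% 3L + 1L
    offset <- (cds_i - 1L) %% 3L + 1L
    # genomic positions of each affected codon, in reading order
    cds_codon <- t(vapply(codon_i, function(ci) (ci - 1L) * 3L + 1:3,
                          integer(3)))
    g_codon <- if (o$strand == "+") {
      matrix(gpos[cds_codon], ncol = 3)
    } else {
      matrix(gpos[n - cds_codon + 1L], ncol = 3)
    }
    ref_codon <- matrix(seqc[g_codon], ncol = 3)
    alt_base <- alt[hit]
    if (o$strand == "-") {
      ref_codon[] <- COMPLEMENT[ref_codon]
      alt_base <- COMPLEMENT[alt_base]
    }
    alt_codon <- ref_codon
    alt_codon[cbind(seq_along(hit), offset)] <- alt_base
    ref_str <- apply(ref_codon, 1, paste, collapse = "")
    alt_str <- apply(alt_codon, 1, paste, collapse = "")
    aa_ref <- Biostrings::GENETIC_CODE[ref_str]
    aa_alt <- Biostrings::GENETIC_CODE[alt_str]
    cls <- ifelse(aa_ref != "*" & aa_alt == "*", "stop_gained",
           ifelse(aa_ref == "*" & aa_alt != "*", "stop_lost",
           ifelse(codon_i == 1L & ref_str == "ATG", "start_lost",
           ifelse(aa_ref == aa_alt, "synonymous", "nonsynonymous"))))
    sev <- EFFECT_SEVERITY[cls]
    ost <- o$segments[1, 1]
    better <- sev > severity[hit] |
      (sev == severity[hit] & ost < tie_start[hit])
    class[hit][better] <- cls[better]
    severity[hit][better] <- sev[better]
    tie_start[hit][better] <- ost
  }
  unname(class)
}

#' @rdname classify_variants
#' @param site single-row site (list or data.frame with `pos`, `alt`,
#'   optionally `ref`).
#' @export
classify_snp <- function(site, genome) {
  classify_variants(as.data.frame(site)[1, , drop = FALSE], genome)
}

#' Tabulate an effect spectrum
#'
#' @param classes character vector of effect classes.
#' @return list of class `"effect_spectrum"` with `counts` (named integer
#'   vector over the full class universe) and `total`.
#' @export
effect_spectrum <- function(classes) {
  bad <- setdiff(unique(classes), EFFECT_CLASSES)
  if (length(bad)) stop("unknown effect class: ", paste(bad, collapse = ", "))
  counts <- table(factor(classes, levels = EFFECT_CLASSES))
  structure(list(counts = setNames(as.integer(counts), names(counts)),
                 total = length(classes)),
            class = "effect_spectrum")
}

#' Lump start/stop classes of a spectrum into one category
#'
#' Reporting granularity option: the three start/stop classes are combined
#' into a single `start_stop` bin while `intergenic`, `synonymous` and
#' `nonsynonymous` stay separate.
#'
#' @param spectrum an [effect_spectrum()]
#' @export
lump_start_stop <- function(spectrum) {
  cnt <- spectrum$counts
  out <- c(cnt[c("intergenic", "synonymous", "nonsynonymous")],
           start_stop = sum(cnt[c("start_lost", "stop_gained", "stop_lost")]))
  structure(list(counts = out, total = spectrum$total),
            class = "effect_spectrum")
}

#' @export
print.effect_spectrum <- function(x, ...) {
  cat("effect_spectrum (total", x$total, "):\n")
  print(x$counts)
  invisible(x)
}

#' Exhaustive mutational null spectrum
#'
#' Enumerates all three possible base changes at every reference position
#' and classifies each one, yielding the effect distribution expected under
#' a uniform per-position mutation probability. The total is always
#' `3 * genome_length`.
#'
#' @param genome a [genome_annotation()] carrying a sequence.
#' @return an [effect_spectrum()]; the per-variant table is attached as
#'   attribute `"variants"` when `keep_variants = TRUE`.
#' @param keep_variants return the full variant-by-variant classification.
#' @export
null_spectrum <- function(genome, keep_variants = FALSE) {
  if (is.null(genome$sequence)) stop("genome annotation carries no sequence")
  seqc <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  L <- genome$genome_length
  pos <- rep(seq_len(L), each = 3)
  alt <- unlist(lapply(seqc, function(b) setdiff(BASES, b)), use.names = FALSE)
  sites <- data.frame(pos = pos, alt = alt, stringsAsFactors = FALSE)
  cls <- classify_variants(sites, genome)
  spec <- effect_spectrum(cls)
  if (keep_variants) {
    sites$ref <- seqc[pos]
    sites$class <- cls
    attr(spec, "variants") <- sites
  }
  spec
}

#' Write an exhaustive null-spectrum VCF
#'
#' Exports every possible SNP with its effect class in the INFO field,
#' plus a class-count TSV.
#'
#' @param genome a [genome_annotation()] with sequence.
#' @param vcf_path output VCF path (plain text).
#' @param tsv_path optional class-count TSV path.
#' @export
write_null_spectrum_vcf <- function(genome, vcf_path, tsv_path = NULL) {
  spec <- null_spectrum(genome, keep_variants = TRUE)
  v <- attr(spec, "variants")
  con <- file(vcf_path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=", genome$contig, ",length=",
                      genome$genome_length, ">"),
               "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Effect class\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO"), collapse = "\t")), con)
  writeLines(paste(genome$contig, v$pos, ".", v$ref, v$alt, ".", ".",
                   paste0("EFF=", v$class), sep = "\t"), con)
  if (!is.null(tsv_path)) {
    write.table(data.frame(class = names(spec$counts), count = spec$counts,
                           row.names = NULL),
                tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(spec)
}

#' Monte-Carlo chi-squared comparison of two effect spectra
#'
#' Pearson's chi-squared test of independence on the 2-by-K table of
#' empirical versus null class counts. Because the empirical total is
#' small, the p-value is obtained by Monte-Carlo resampling of tables with
#' fixed margins under independence, with the add-one estimator
#' `(1 + #{X2_sim >= X2_obs}) / (n_mc + 1)`. Classes with zero counts in
#' both spectra are dropped. Seeded and reproducible.
#'
#' @param empirical,null [effect_spectrum()] objects over the same class
#'   universe.
#' @param n_mc number of Monte-Carlo tables.
#' @param seed integer seed.
#' @return list with `statistic` (Pearson X2) and `p.value`.
#' @export
spectrum_test <- function(empirical, null, n_mc = 10000, seed = 1) {
  if (!identical(names(empirical$counts), names(null$counts)))
    stop("spectra must share one class universe")
  if (empirical$total < 1) stop("empirical spectrum is empty")
  keep <- empirical$counts + null$counts > 0
  m <- rbind(empirical = empirical$counts[keep], null = null$counts[keep])
  res <- with_seed(seed, suppressWarnings(
    stats::chisq.test(m, simulate.p.value = TRUE, B = n_mc)))
  list(statistic = unname(res$statistic), p.value = res$p.value)
}

# evaluate expr under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Fraction of the genome covered by no ORF
#'
#' @param genome a [genome_annotation()] (sequence not required).
#' @return fraction in `[0, 1]` of positions outside every ORF segment.
#' @export
intergenic_fraction <- function(genome) {
  covered <- logical(genome$genome_length)
  for (o in genome$orfs) {
    for (k in seq_len(nrow(o$segments))) {
      covered[o$segments[k, 1]:o$segments[k, 2]] <- TRUE
    }
  }
  mean(!covered)
}
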
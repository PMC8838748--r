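#' Read pooled variant calls from a VCF into a variant table
#'
#' Consumes a VCF 4.2 with per-sample read-count FORMAT fields, as produced
#' by pooled-continuous variant callers. Only biallelic SNP records with
#' `QUAL >= min_qual` are retained; records with several alternative bases
#' are decomposed into one site per alternative base, with the reads
#' supporting the other (non-focal) alternatives assigned to the reference
#' count, so each site's frequency refers to that base change alone. Indel
#' and other non-SNP alleles are skipped with a logged count.
#'
#' Count fields: `RO`/`AO` (reference / per-allele alternative observation
#' counts) are used when present, otherwise the allele-depth field `AD`.
#'
#' @param vcf_path path to a VCF (plain text or gzip).
#' @param samples a [sample_sheet()]; every sample must be present in the
#'   VCF (extra VCF samples are ignored).
#' @param min_depth minimum depth for an allele-frequency estimate
#'   (entries below are missing, not zero).
#' @param min_qual minimum caller quality; records below are dropped at
#'   read time. Pass 0 to keep everything and let
#'   [apply_filter_cascade()] flag low-quality sites instead.
#' @return a [variant_table()]
#' @export
read_variant_table <- function(vcf_path, samples, min_depth = 10, min_qual = 20) {
  samples <- sample_sheet(as.data.frame(samples))
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  vcf_samples <- colnames(vcf@gt)[-1]
  absent <- setdiff(samples$sample_id, vcf_samples)
  if (length(absent))
    stop("sample(s) in sheet absent from VCF: ", paste(absent, collapse = ", "))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  nrec <- nrow(fix)
  if (nrec == 0)
    return(variant_table(empty_sites(), samples,
                         matrix(0L, 0, nrow(samples)), matrix(0L, 0, nrow(samples)),
                         min_depth = min_depth))
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  qual[is.na(qual)] <- 0

  fmt1 <- strsplit(vcf@gt[1, "FORMAT"], ":")[[1]]
  use_ro <- all(c("RO", "AO") %in% fmt1)
  if (use_ro) {
    ro <- vcfR::extract.gt(vcf, "RO", as.numeric = TRUE)
    ao_raw <- vcfR::extract.gt(vcf, "AO")
  } else if ("AD" %in% fmt1) {
    ad_raw <- vcfR::extract.gt(vcf, "AD")
  } else {
    stop("VCF FORMAT must provide RO/AO or AD read counts")
  }

  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  sites <- list(); refc <- list(); altc <- list()
  n_skipped <- 0L
  for (i in seq_len(nrec)) {
    if (qual[i] < min_qual) next
    ref <- toupper(fix[i, "REF"])
    rec_alts <- toupper(alts[[i]])
    if (!ref %in% BASES) { n_skipped <- n_skipped + 1L; next }
    snp_idx <- which(rec_alts %in% BASES & rec_alts != ref)
    if (length(snp_idx) < length(rec_alts)) n_skipped <- n_skipped + 1L
    if (!length(snp_idx)) next
    k <- length(rec_alts)
    if (use_ro) {
      ao_i <- parse_multi(ao_raw[i, samples$sample_id], k)
      ro_i <- ro[i, samples$sample_id]
      ro_i[is.na(ro_i)] <- 0
      tot_alt <- rowSums(ao_i)
    } else {
      ad_i <- parse_multi(ad_raw[i, samples$sample_id], k + 1L)
      ro_i <- ad_i[, 1]
      ao_i <- ad_i[, -1, drop = FALSE]
      tot_alt <- rowSums(ao_i)
    }
    for (j in snp_idx) {
      sites[[length(sites) + 1L]] <- data.frame(
        contig = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
        ref = ref, alt = rec_alts[j], qual = qual[i],
        stringsAsFactors = FALSE)
      altc[[length(altc) + 1L]] <- ao_i[, j]
      # residual non-focal alternative reads count as reference support
      refc[[length(refc) + 1L]] <- ro_i + tot_alt - ao_i[, j]
    }
  }
  if (n_skipped > 0)
    message("read_variant_table: skipped ", n_skipped,
            " record(s) with non-SNP allele(s)")
  if (!length(sites))
    return(variant_table(empty_sites(), samples,
                         matrix(0L, 0, nrow(samples)), matrix(0L, 0, nrow(samples)),
                         min_depth = min_depth))
  variant_table(do.call(rbind, sites), samples,
                do.call(rbind, refc), do.call(rbind, altc),
                min_depth = min_depth)
}

empty_sites <- function() {
  data.frame(contig = character(), pos = integer(), ref = character(),
             alt = character(), qual = numeric(), stringsAsFactors = FALSE)
}

# split "a,b,c" per-sample strings into an n_samples x k numeric matrix
parse_multi <- function(x, k) {
  parts <- strsplit(ifelse(is.na(x), "", x), ",", fixed = TRUE)
  out <- matrix(0, nrow = length(x), ncol = k)
  for (s in seq_along(parts)) {
    v <- suppressWarnings(as.numeric(parts[[s]]))
    v[is.na(v)] <- 0
    out[s, seq_len(min(k, length(v)))] <- v[seq_len(min(k, length(v)))]
  }
  out
}

#' Write a variant table to VCF or TSV
#'
#' Both dialects are round-trip safe: reading the written file back with
#' [read_variant_table()] / [read_count_table()] (with `min_qual = 0`)
#' reproduces counts, quals and missingness exactly. The TSV dialect has one
#' row per site and one `"ref:alt"` integer pair per sample cell, which keeps
#' fixtures human-diffable.
#'
#' @param table a [variant_table()]
#' @param path output path
#' @param format `"vcf"` or `"tsv"`
#' @export
write_variant_table <- function(table, path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (n_sites(table) == 0) { # header-only file
      writeLines(paste(c(names(table$sites), table$samples$sample_id),
                       collapse = "\t"), path)
      return(invisible(path))
    }
    df <- table$sites
    for (s in seq_len(n_samples(table))) {
      df[[table$samples$sample_id[s]]] <-
        paste0(table$ref_count[, s], ":", table$alt_count[, s])
    }
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "##fileformat=VCFv4.2",
      paste0("##source=poolER"),
      paste0("##contig=<ID=", unique(table$sites$contig), ">"),
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
      "##FORMAT=<ID=RO,Number=1,Type=Integer,Description=\"Reference observation count\">",
      "##FORMAT=<ID=AO,Number=A,Type=Integer,Description=\"Alternate observation count\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", table$samples$sample_id), collapse = "\t")), con)
    if (n_sites(table)) {
      dp <- depth(table)
      cells <- matrix(paste0(dp, ":", table$ref_count, ":", table$alt_count),
                      nrow = n_sites(table))
      lines <- vapply(seq_len(n_sites(table)), function(i) {
        paste(c(table$sites$contig[i], table$sites$pos[i], ".",
                table$sites$ref[i], table$sites$alt[i],
                format(table$sites$qual[i], digits = 15, trim = TRUE,
                       scientific = FALSE),
                ".", ".", "DP:RO:AO", cells[i, ]), collapse = "\t")
      }, "")
      writeLines(lines, con)
    }
  }
  invisible(path)
}

#' Read the TSV count-table dialect written by [write_variant_table()]
#'
#' @inheritParams read_variant_table
#' @param path TSV with site columns `contig`, `pos`, `ref`, `alt`, `qual`
#'   followed by one `"ref:alt"` column per sample.
#' @export
read_count_table <- function(path, samples, min_depth = 10, min_qual = 0) {
  samples <- sample_sheet(as.data.frame(samples))
  df <- read.delim(path, colClasses = "character", check.names = FALSE)
  absent <- setdiff(samples$sample_id, names(df))
  if (length(absent))
    stop("sample(s) in sheet absent from count table: ",
         paste(absent, collapse = ", "))
  sites <- data.frame(contig = df$contig, pos = as.integer(df$pos),
                      ref = df$ref, alt = df$alt, qual = as.numeric(df$qual),
                      stringsAsFactors = FALSE)
  keep <- which(sites$qual >= min_qual)
  sites <- sites[keep, , drop = FALSE]
  nk <- length(keep)
  refc <- altc <- matrix(0L, nk, nrow(samples))
  for (s in seq_len(nrow(samples))) {
    pair <- strsplit(df[[samples$sample_id[s]]][keep], ":", fixed = TRUE)
    refc[, s] <- vapply(pair, function(p) as.integer(p[1]), 1L)
    altc[, s] <- vapply(pair, function(p) as.integer(p[2]), 1L)
  }
  variant_table(sites, samples, refc, altc, min_depth = min_depth)
}

#' Read an ORF annotation from GFF3 or TSV
#'
#' GFF3 input: CDS features are grouped by their `Parent` attribute (falling
#' back to `ID`/`Name`), so multi-segment ORFs are assembled; strand comes
#' from the strand column. TSV input: header columns `name`, `start`, `end`
#' and optionally `strand`; several rows with the same name form a
#' multi-segment ORF. When the TSV has no strand column, direction is
#' inferred from the gene-name suffix (`R` = `+`, `L` = `-`), the PBCV-1
#' naming convention; an explicit strand always wins.
#'
#' @param path GFF3 or TSV file.
#' @param genome_length contig length in bp. Required for TSV; for GFF3 it
#'   defaults to the `##sequence-region` pragma (or the maximum feature end).
#' @param contig contig name (defaults to the GFF3 seqid or `"contig_1"`).
#' @param sequence optional reference sequence string.
#' @return a [genome_annotation()]
#' @export
read_annotation <- function(path, genome_length = NULL, contig = NULL,
                            sequence = NULL) {
  first <- readLines(path, n = 1L)
  is_gff <- grepl("^##gff-version", first) ||
    tolower(tools::file_ext(path)) %in% c("gff", "gff3")
  if (is_gff) {
    gr <- rtracklayer::import(path)
    md <- S4Vectors::mcols(gr)
    feat_type <- as.character(md$type)
    take <- feat_type == "CDS"
    if (!any(take)) take <- rep(TRUE, length(gr))
    gr <- gr[take]; md <- S4Vectors::mcols(gr)
    grp <- NULL
    if ("Parent" %in% names(md)) {
      par <- md$Parent
      grp <- vapply(seq_along(par), function(i) {
        p <- unlist(par[i])
        if (length(p)) as.character(p[1]) else NA_character_
      }, "")
    }
    if (is.null(grp) || all(is.na(grp))) {
      for (alt in c("ID", "Name", "gene")) {
        if (alt %in% names(md)) { grp <- as.character(md[[alt]]); break }
      }
    }
    if (is.null(grp)) grp <- as.character(seq_along(gr))
    grp[is.na(grp)] <- paste0("feature_", which(is.na(grp)))
    if (is.null(contig)) contig <- as.character(GenomicRanges::seqnames(gr)[1])
    if (is.null(genome_length)) {
      pragma <- grep("^##sequence-region", readLines(path), value = TRUE)
      if (length(pragma)) {
        genome_length <- as.integer(utils::tail(strsplit(pragma[1], "\\s+")[[1]], 1))
      } else {
        genome_length <- max(GenomicRanges::end(gr))
      }
    }
    orfs <- lapply(split(seq_along(gr), grp), function(idx) {
      segs <- cbind(GenomicRanges::start(gr)[idx], GenomicRanges::end(gr)[idx])
      strand <- as.character(GenomicRanges::strand(gr)[idx[1]])
      if (!strand %in% c("+", "-")) strand <- "+"
      orf(grp[idx[1]], segs, strand)
    })
  } else {
    df <- read.delim(path, check.names = FALSE,
                     colClasses = "character")
    req <- c("name", "start", "end")
    if (!all(req %in% names(df)))
      stop("annotation TSV needs columns name, start, end")
    if (is.null(genome_length))
      stop("genome_length is required for TSV annotations")
    if (is.null(contig)) contig <- "contig_1"
    df$start <- as.integer(gsub(",", "", df$start))
    df$end <- as.integer(gsub(",", "", df$end))
    orfs <- lapply(split(seq_len(nrow(df)), df$name), function(idx) {
      strand <- if ("strand" %in% names(df) && !is.na(df$strand[idx[1]]) &&
                    df$strand[idx[1]] %in% c("+", "-", "−")) {
        ifelse(df$strand[idx[1]] == "−", "-", df$strand[idx[1]])
      } else {
        infer_strand(df$name[idx[1]])
      }
      orf(df$name[idx[1]], cbind(df$start[idx], df$end[idx]), strand)
    })
  }
  orfs <- orfs[order(vapply(orfs, function(o) o$segments[1, 1], 1L))]
  genome_annotation(contig, genome_length, orfs, sequence = sequence)
}

# PBCV-1 gene names encode direction: trailing R = rightward (+), L = leftward (-)
infer_strand <- function(name) {
  if (grepl("R$", name)) return("+")
  if (grepl("L$", name)) return("-")
  stop("cannot infer strand from ORF name '", name,
       "'; provide a strand column")
}

#' Read a reference genome from FASTA
#'
#' @param path FASTA file; the first record is used.
#' @return list with `contig`, `genome_length` and `sequence` (upper-case
#'   string), ready to pass to [genome_annotation()].
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("empty FASTA: ", path)
  list(contig = sub("\\s.*", "", names(ss)[1]),
       genome_length = Biostrings::width(ss)[1],
       sequence = toupper(as.character(ss[[1]])))
}

#' Write a genome (annotation with sequence) to FASTA
#' @param genome a [genome_annotation()] carrying a sequence
#' @param path output path
#' @export
write_reference <- function(genome, path) {
  if (is.null(genome$sequence)) stop("annotation carries no sequence")
  ss <- Biostrings::DNAStringSet(genome$sequence)
  names(ss) <- genome$contig
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
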
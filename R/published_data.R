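#' Published PBCV-1 experiment summary tables
#'
#' Small summary tables transcribed from a replicated Chlorovirus
#' PBCV-1 / *Chlorella variabilis* chemostat coevolution experiment,
#' shipped with the package so that its statistics can be exercised on
#' the real study's printed summaries without access to the raw reads:
#'
#' * `pbcv1_orf_table()`: the eighteen ORFs of the PBCV-1 reference genome
#'   (NC_000852.5) in which variable sites were found — name, 1-based
#'   coordinates, length, number of distinct variable sites and total
#'   number of SNP observations across replicates.
#' * `pbcv1_replicate_table()`: per-replicate endpoint summaries — the
#'   demographic treatment, number of polymorphic sites at the last
#'   sequenced time point and nucleotide diversity.
#'
#' @return a data.frame.
#' @export
pbcv1_orf_table <- function() {
  read.delim(system.file("extdata", "pbcv1_orf_variants.tsv",
                         package = "poolER"))
}

#' @rdname pbcv1_orf_table
#' @export
pbcv1_replicate_table <- function() {
  read.delim(system.file("extdata", "pbcv1_replicate_summary.tsv",
                         package = "poolER"))
}

#' Genome annotation for the PBCV-1 enrichment scan
#'
#' Builds a [genome_annotation()] of the full 330,611 bp PBCV-1 reference
#' containing the eighteen ORFs with observed variation at their true
#' coordinates plus synthetic filler ORFs (no variable sites) so that the
#' total equals the 812 ORFs of the reference annotation. Filler
#' coordinates are synthetic placeholders: ORFs with zero variable sites
#' enter the Fisher/Holm scan with p = 1 regardless of their length or
#' position, so only their number matters.
#'
#' @param n_orfs total number of ORFs (default 812).
#' @param genome_length reference length in bp (default 330,611).
#' @param filler_length length assigned to filler ORFs.
#' @return a [genome_annotation()] (no sequence).
#' @export
pbcv1_annotation <- function(n_orfs = 812, genome_length = 330611,
                             filler_length = 300) {
  tab <- pbcv1_orf_table()
  orfs <- lapply(seq_len(nrow(tab)), function(i) {
    orf(tab$name[i], cbind(tab$start[i], tab$end[i]),
        infer_strand(tab$name[i]))
  })
  n_fill <- n_orfs - nrow(tab)
  if (n_fill > 0) {
    # tile filler ORFs into a stretch with no variable sites; their
    # coordinates are inert (m_orf = 0 gives p = 1 whatever the length)
    fill <- suppressWarnings(lapply(seq_len(n_fill), function(i) {
      start <- 83001L + (i - 1L) %% 250L
      orf(sprintf("fillerR_%03d", i), cbind(start, start + filler_length - 1L),
          "+")
    }))
    orfs <- c(orfs, fill)
  }
  genome_annotation("NC_000852.5", genome_length, orfs)
}

#' Deterministic variable-site positions matching the published counts
#'
#' Spreads each ORF's number of distinct variable sites evenly across the
#' ORF's span and adds one intergenic site, reproducing the study's
#' genome-wide configuration (67 sites inside the eighteen ORFs plus one
#' intergenic site).
#'
#' @return sorted integer positions.
#' @export
pbcv1_snp_positions <- function() {
  tab <- pbcv1_orf_table()
  pos <- unlist(lapply(seq_len(nrow(tab)), function(i) {
    k <- tab$n_variable_sites[i]
    unique(round(seq(tab$start[i], tab$end[i], length.out = k + 2))[2:(k + 1)])
  }))
  intergenic <- 100000L # inside no annotated ORF
  sort(unique(c(as.integer(pos), intergenic)))
}
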
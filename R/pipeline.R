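#' Endpoint sample index per replicate
#'
#' @param samples a [sample_sheet()]
#' @return integer vector (named by replicate) of row indices of each
#'   replicate's last sequenced time point (ancestors excluded).
#' @export
endpoint_samples <- function(samples) {
  evolved <- which(samples$treatment != "ancestor")
  vapply(split(evolved, samples$replicate_id[evolved]), function(idx) {
    idx[which.max(samples$day[idx])]
  }, 1L)
}

#' Run the full analysis pipeline and summarize headline statistics
#'
#' Applies the artifact-filter cascade, computes per-sample diversity and
#' per-site repeatability/selection estimates, compares the two
#' demographic treatments at the endpoint (Poisson log-linear on the
#' number of polymorphic sites; Welch t on nucleotide diversity), and —
#' when an annotation with sequence is supplied — classifies SNP effects,
#' tests the empirical effect spectrum against the exhaustive mutational
#' null, compares effect classes, and scans ORFs for excess variation.
#'
#' @param table a [variant_table()]
#' @param annotation optional [genome_annotation()] (with sequence for the
#'   effect analyses; without sequence only the ORF scan runs).
#' @param cfg a [filter_config()]
#' @param L_eff reliably evaluated sites for diversity normalization.
#' @param gen_per_day generations per day.
#' @param alpha family-wise error rate for the ORF scan.
#' @param n_mc Monte-Carlo tables for the spectrum test.
#' @param seed seed for the spectrum test.
#' @return list of class `"pooler_summary"`: `filter` (cascade output),
#'   `diversity`, `repeatability`, `treatment` (endpoint comparisons),
#'   and optionally `effects`, `spectrum`, `class_comparison`, `orf_scan`.
#' @export
run_pipeline <- function(table, annotation = NULL, cfg = filter_config(),
                         L_eff = 3e5, gen_per_day = 75 / 52, alpha = 0.05,
                         n_mc = 10000, seed = 1) {
  cascade <- apply_filter_cascade(table, cfg)
  ft <- cascade$table
  out <- list(filter = cascade)
  if (n_sites(ft) == 0) {
    out$diversity <- diversity(ft, L_eff)
    return(structure(out, class = "pooler_summary"))
  }
  div <- diversity(ft, L_eff)
  out$diversity <- div

  ends <- endpoint_samples(ft$samples)
  end_div <- div[ends, , drop = FALSE]
  end_treat <- ft$samples$treatment[ends]
  out$treatment <- local({
    weak <- end_treat == "weak_demography"
    strong <- end_treat == "strong_demography"
    if (sum(weak) >= 2 && sum(strong) >= 2) {
      list(p_n_polymorphic = poisson_loglinear_two_group(
             end_div$n_polymorphic[weak], end_div$n_polymorphic[strong]),
           p_diversity = welch_t_two_sided(end_div$pi[weak],
                                           end_div$pi[strong]))
    } else NULL
  })

  effects <- NULL
  if (!is.null(annotation) && !is.null(annotation$sequence)) {
    effects <- classify_variants(ft$sites, annotation)
    out$effects <- data.frame(ft$sites[, c("contig", "pos", "ref", "alt")],
                              effect_class = effects,
                              stringsAsFactors = FALSE)
    emp <- effect_spectrum(effects)
    nul <- null_spectrum(annotation)
    out$spectrum <- c(spectrum_test(emp, nul, n_mc = n_mc, seed = seed),
                      list(empirical = emp, null = nul))
  }
  out$repeatability <- repeatability(ft, gen_per_day = gen_per_day,
                                     effects = effects)
  if (!is.null(effects))
    out$class_comparison <- suppressWarnings(class_comparison(out$repeatability))
  if (!is.null(annotation) && length(annotation$orfs))
    out$orf_scan <- orf_scan(ft$sites$pos, annotation, alpha = alpha)
  structure(out, class = "pooler_summary")
}

#' Headline statistics of a pipeline run as a plain list
#'
#' @param summary a result of [run_pipeline()]
#' @return named list of scalar statistics suitable for JSON export.
#' @export
summary_stats <- function(summary) {
  out <- list(
    n_input_sites = nrow(summary$filter$report),
    n_retained_sites = sum(summary$filter$report$retained),
    mean_repeatability = if (!is.null(summary$repeatability))
      mean(summary$repeatability$n_replicates_present) else NULL,
    p_treatment_n_polymorphic = summary$treatment$p_n_polymorphic,
    p_treatment_diversity = summary$treatment$p_diversity,
    p_spectrum = summary$spectrum$p.value,
    p_class_repeatability = summary$class_comparison$p_repeatability,
    p_class_selection = summary$class_comparison$p_selection,
    n_significant_orfs = if (!is.null(summary$orf_scan))
      sum(summary$orf_scan$significant) else NULL,
    significant_orfs = if (!is.null(summary$orf_scan))
      summary$orf_scan$orf[summary$orf_scan$significant] else NULL)
  out[!vapply(out, is.null, TRUE)]
}

#' Write pipeline outputs to a directory
#'
#' Emits the filter report and per-test table, per-sample diversity,
#' per-site repeatability, effect table, ORF scan (as TSV) and the
#' headline statistics as JSON.
#'
#' @param summary result of [run_pipeline()]
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_pipeline_outputs <- function(summary, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    if (!is.null(x))
      write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                  row.names = FALSE)
  }
  write_filter_report(summary$filter, file.path(dir, "filter_report.tsv"),
                      file.path(dir, "filter_tests.tsv"))
  tsv(summary$diversity, "diversity.tsv")
  tsv(summary$repeatability, "repeatability.tsv")
  tsv(summary$effects, "effects.tsv")
  tsv(summary$orf_scan, "orf_scan.tsv")
  jsonlite::write_json(summary_stats(summary),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.pooler_summary <- function(x, ...) {
  cat("pooler pipeline summary\n")
  cat(sprintf("  sites: %d in, %d retained\n", nrow(x$filter$report),
              sum(x$filter$report$retained)))
  st <- summary_stats(x)
  for (k in setdiff(names(st), c("n_input_sites", "n_retained_sites"))) {
    v <- st[[k]]
    cat(sprintf("  %s: %s\n", k,
                paste(if (is.numeric(v)) signif(v, 4) else v, collapse = ", ")))
  }
  invisible(x)
}
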
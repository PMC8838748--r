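#' Filter configuration for the artifact-removal cascade
#'
#' Defaults are the thresholds used throughout the package: caller quality
#' 20, at most 10% missing frequency estimates per site, FDR 0.05 for the
#' binomial constancy test, and the `(0.01, 0.99]` frequency band that
#' defines "polymorphic" for the batch-wide polymorphism rule.
#'
#' @param min_qual minimum caller quality.
#' @param max_missing_fraction maximum tolerated fraction of missing
#'   allele-frequency estimates across samples.
#' @param fdr_alpha FDR level for the constancy test.
#' @param af_lower,af_upper the polymorphism band: a frequency estimate `f`
#'   counts as polymorphic when `af_lower < f <= af_upper`.
#' @return list of class `"filter_config"`
#' @export
filter_config <- function(min_qual = 20, max_missing_fraction = 0.10,
                          fdr_alpha = 0.05, af_lower = 0.01, af_upper = 0.99) {
  stopifnot(min_qual >= 0, max_missing_fraction >= 0, max_missing_fraction <= 1,
            fdr_alpha > 0, fdr_alpha < 1, af_lower < af_upper)
  structure(list(min_qual = min_qual,
                 max_missing_fraction = max_missing_fraction,
                 fdr_alpha = fdr_alpha, af_lower = af_lower,
                 af_upper = af_upper),
            class = "filter_config")
}

#' Two-sided exact binomial p-value (minimum-likelihood convention)
#'
#' The two-sided p-value is the sum of probabilities of all outcomes whose
#' point probability does not exceed that of the observed count (with the
#' customary `1 + 1e-7` relative slack against floating-point ties), the
#' convention used by mainstream exact binomial tests.
#'
#' @param x observed successes.
#' @param n number of trials.
#' @param p null success probability.
#' @return p-value in `[0, 1]`.
#' @export
binom_test_minlike <- function(x, n, p) {
  stopifnot(length(x) == 1, length(n) == 1, x >= 0, x <= n, p >= 0, p <= 1)
  if (n == 0) return(1)
  d <- dbinom(0:n, n, p)
  min(1, sum(d[d <= d[x + 1] * (1 + 1e-7)]))
}

#' Binomial constancy test for one site in one replicate
#'
#' For a clonal population under directional selection it is highly
#' improbable that a genuine polymorphism keeps a constant frequency over
#' time, so constancy is diagnostic of an artifact. The test pools the
#' replicate's reads to estimate a single success probability
#' `p_hat = sum(alt) / sum(depth)` and asks, per time point, whether the
#' observed alternative count could be a draw from
#' `Binomial(depth, p_hat)` (two-sided exact test, minimum-likelihood
#' convention).
#'
#' @param alt_count,depth integer vectors over the replicate's time points
#'   (missing time points excluded by the caller).
#' @return numeric vector of p-values, one per time point (empty if no
#'   time point has positive depth).
#' @export
binomial_constancy_test <- function(alt_count, depth) {
  stopifnot(length(alt_count) == length(depth),
            all(alt_count >= 0), all(depth >= alt_count))
  keep <- which(depth > 0)
  if (!length(keep)) return(numeric(0))
  alt_count <- alt_count[keep]; depth <- depth[keep]
  p_hat <- sum(alt_count) / sum(depth)
  vapply(seq_along(depth),
         function(i) binom_test_minlike(alt_count[i], depth[i], p_hat),
         1)
}

#' Missing-data filter
#'
#' Flags sites whose number of missing allele-frequency estimates exceeds
#' `floor(max_missing_fraction * n_samples)` — with 35 samples and the 10%
#' default this is "more than 3 missing values".
#'
#' @param table a [variant_table()]
#' @param cfg a [filter_config()]
#' @return logical per-site flag (`TRUE` = remove)
#' @export
filter_missing <- function(table, cfg = filter_config()) {
  if (n_samples(table) < 1) stop("table has no samples")
  n_missing <- rowSums(is.na(allele_freq(table)))
  unname(n_missing > floor(cfg$max_missing_fraction * n_samples(table)))
}

#' Constant-frequency (binomial) artifact filter
#'
#' Runs [binomial_constancy_test()] for every site within every
#' evolutionary replicate (ancestor samples are excluded; frequency change
#' "over time" is a within-replicate notion), pools each site's p-values
#' across replicates and time points, applies a Benjamini-Hochberg
#' adjustment within that per-site family, and flags the site for removal
#' when no adjusted value falls below `fdr_alpha` — i.e. when there is no
#' evidence anywhere that the allele changed in frequency.
#'
#' @param table a [variant_table()]
#' @param cfg a [filter_config()]
#' @return list with `flag` (logical per site, `TRUE` = remove) and
#'   `tests`, a data.frame of the individual tests (site key, replicate,
#'   day, counts, `p`, BH-adjusted `q`).
#' @export
filter_constant <- function(table, cfg = filter_config()) {
  dp <- depth(table)
  af <- allele_freq(table)
  evolved <- table$samples$treatment != "ancestor"
  reps <- split(which(evolved), table$samples$replicate_id[evolved])
  keys <- site_key(table)
  flag <- logical(n_sites(table))
  tests <- list()
  for (i in seq_len(n_sites(table))) {
    p_all <- numeric(0); meta <- list()
    for (r in names(reps)) {
      cols <- reps[[r]][order(table$samples$day[reps[[r]]])]
      ok <- cols[!is.na(af[i, cols])]   # time points with a frequency estimate
      if (!length(ok)) next
      p <- binomial_constancy_test(table$alt_count[i, ok], dp[i, ok])
      p_all <- c(p_all, p)
      meta[[length(meta) + 1L]] <- data.frame(
        site = keys[i], replicate_id = r, day = table$samples$day[ok],
        alt_count = table$alt_count[i, ok], depth = dp[i, ok], p = p,
        stringsAsFactors = FALSE)
    }
    if (!length(p_all)) { flag[i] <- TRUE; next }
    q <- p.adjust(p_all, method = "BH")
    flag[i] <- min(q) >= cfg$fdr_alpha
    m <- do.call(rbind, meta); m$q <- q
    tests[[length(tests) + 1L]] <- m
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(site = character(), replicate_id = character(), day = numeric(),
               alt_count = integer(), depth = integer(), p = numeric(),
               q = numeric(), stringsAsFactors = FALSE)
  rownames(tests) <- NULL
  list(flag = flag, tests = tests)
}

#' Batch-wide polymorphism filter
#'
#' Spurious variation caused by complex genomic regions or duplications
#' tends to appear as a consistently polymorphic allele in every library,
#' which is highly unlikely for genuine variation across independent
#' replicates and time points. A site is flagged when, in at least one
#' sequencing batch with at least two non-missing samples, every
#' non-missing frequency estimate falls inside the polymorphism band
#' `(af_lower, af_upper]`.
#'
#' @param table a [variant_table()]
#' @param cfg a [filter_config()]
#' @return logical per-site flag (`TRUE` = remove)
#' @export
filter_ubiquitous_polymorphism <- function(table, cfg = filter_config()) {
  af <- allele_freq(table)
  flag <- logical(n_sites(table))
  for (b in split(seq_len(n_samples(table)), table$samples$batch_id)) {
    sub <- af[, b, drop = FALSE]
    n_obs <- rowSums(!is.na(sub))
    n_poly <- rowSums(!is.na(sub) & sub > cfg$af_lower & sub <= cfg$af_upper)
    flag <- flag | (n_obs >= 2 & n_poly == n_obs)
  }
  unname(flag)
}

#' Apply the full artifact-filter cascade
#'
#' Sites below `min_qual` are flagged `low_qual`; the three artifact flags
#' (excess missingness, binomial constancy, batch-wide polymorphism) are
#' computed independently on the quality-passing sites, so one site can
#' carry several flags and per-criterion removal counts are reportable.
#' A site is retained iff it carries no flag.
#'
#' @param table a [variant_table()] (read with `min_qual = 0` if low-quality
#'   sites should appear in the report).
#' @param cfg a [filter_config()]
#' @return list with `table` (retained sites), `report` (per-site flags,
#'   one row per input site) and `tests` (the constancy-test p/q table).
#' @export
apply_filter_cascade <- function(table, cfg = filter_config()) {
  low_qual <- table$sites$qual < cfg$min_qual
  n <- n_sites(table)
  report <- data.frame(table$sites[, c("contig", "pos", "ref", "alt")],
                       low_qual = low_qual,
                       excess_missing = rep(NA, n),
                       constant_binomial = rep(NA, n),
                       ubiquitous_polymorphic = rep(NA, n),
                       retained = rep(FALSE, n),
                       stringsAsFactors = FALSE)
  pass <- which(!low_qual)
  tests <- NULL
  if (length(pass)) {
    sub <- subset_sites(table, pass)
    f_miss <- filter_missing(sub, cfg)
    f_const <- filter_constant(sub, cfg)
    f_ubiq <- filter_ubiquitous_polymorphism(sub, cfg)
    report$excess_missing[pass] <- f_miss
    report$constant_binomial[pass] <- f_const$flag
    report$ubiquitous_polymorphic[pass] <- f_ubiq
    report$retained[pass] <- !f_miss & !f_const$flag & !f_ubiq
    tests <- f_const$tests
  }
  list(table = subset_sites(table, which(report$retained)),
       report = report, tests = tests)
}

#' Write a filter report (and its per-test table) to TSV
#'
#' @param cascade result of [apply_filter_cascade()]
#' @param report_path path for the per-site flag table.
#' @param tests_path optional path for the per-test p/q table.
#' @export
write_filter_report <- function(cascade, report_path, tests_path = NULL) {
  write.table(cascade$report, report_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(tests_path) && !is.null(cascade$tests))
    write.table(cascade$tests, tests_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(report_path)
}
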
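#' Expected heterozygosity (nucleotide diversity) per sample
#'
#' Diversity is computed from the derived allele frequencies at the variable
#' sites and normalized by the number of reliably evaluated genomic sites
#' `L_eff`, so that populations with different numbers of called sites stay
#' comparable: `pi = sum(2 f (1 - f)) / L_eff`. Fixed alleles (`f = 1`)
#' count as polymorphic sites (frequency above zero) but contribute nothing
#' to heterozygosity. Missing estimates are skipped per sample.
#'
#' @param table a [variant_table()]
#' @param L_eff number of reliably evaluated sites (default `3e5`).
#' @return data.frame with `sample_id`, `n_polymorphic`, `pi`.
#' @export
diversity <- function(table, L_eff = 3e5) {
  if (L_eff <= 0) stop("L_eff must be positive")
  af <- allele_freq(table)
  data.frame(
    sample_id = table$samples$sample_id,
    n_polymorphic = as.integer(colSums(af > 0, na.rm = TRUE)),
    pi = colSums(2 * af * (1 - af), na.rm = TRUE) / L_eff,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Effective selection coefficient from two frequencies
#'
#' The per-generation log frequency ratio,
#' `s_eff = ln(f_end / f_start) / delta_g`, i.e. the average extra
#' per-generation growth of the lineage carrying the allele relative to a
#' lineage whose frequency stays exactly constant. It is used as a
#' normalized measure of mean frequency change; it equals the Malthusian
#' selection coefficient while both frequencies are far from 1 and
#' understates it as the allele approaches fixation. Frequencies below
#' `f_floor` (the caller's detection threshold) are floored so that alleles
#' absent at the start still get a finite estimate.
#'
#' @param f_start,f_end frequencies in `[0, 1]` (vectorized).
#' @param delta_g generations elapsed (> 0).
#' @param f_floor detection-threshold floor (default 0.002).
#' @param form `"log_ratio"` (default) or `"logit"`, which uses the log
#'   odds ratio instead and does not saturate near fixation.
#' @return numeric vector of `s_eff` values.
#' @export
selection_coefficient <- function(f_start, f_end, delta_g, f_floor = 0.002,
                                  form = c("log_ratio", "logit")) {
  form <- match.arg(form)
  if (any(delta_g <= 0)) stop("delta_g must be positive")
  stopifnot(all(f_start >= 0 & f_start <= 1, na.rm = TRUE),
            all(f_end >= 0 & f_end <= 1, na.rm = TRUE))
  a <- pmax(f_start, f_floor)
  b <- pmax(f_end, f_floor)
  if (form == "logit") {
    a <- pmin(a, 1 - f_floor); b <- pmin(b, 1 - f_floor)
    log(b / (1 - b) * (1 - a) / a) / delta_g
  } else {
    log(b / a) / delta_g
  }
}

#' Cross-replicate repeatability and mean frequency change per site
#'
#' Repeatability of a mutation is the number of evolutionary replicates in
#' whose endpoint population (each replicate's last sequenced time point)
#' it segregates at a frequency above zero. For each site the effective
#' selection coefficient is computed per replicate between the replicate's
#' first and last time point and averaged over the replicates where the
#' site is present at the endpoint.
#'
#' @param table a [variant_table()] (ancestor samples are ignored).
#' @param gen_per_day generations per day used to convert the day span into
#'   generations (default 75/52: seventy-five generations over the 52-day
#'   coevolution window).
#' @param f_floor detection floor passed to [selection_coefficient()].
#' @param effects optional character vector of per-site effect classes
#'   (e.g. from [classify_variants()]) carried through to the output.
#' @return data.frame with one row per site: site identity,
#'   `n_replicates_present`, `mean_s_eff` and optionally `effect_class`.
#' @export
repeatability <- function(table, gen_per_day = 75 / 52, f_floor = 0.002,
                          effects = NULL) {
  af <- allele_freq(table)
  evolved <- which(table$samples$treatment != "ancestor")
  if (!length(evolved)) stop("no non-ancestor samples in table")
  reps <- split(evolved, table$samples$replicate_id[evolved])
  present <- matrix(FALSE, n_sites(table), length(reps))
  s_eff <- matrix(NA_real_, n_sites(table), length(reps))
  for (r in seq_along(reps)) {
    cols <- reps[[r]][order(table$samples$day[reps[[r]]])]
    first <- cols[1]; last <- cols[length(cols)]
    d_g <- (table$samples$day[last] - table$samples$day[first]) * gen_per_day
    f_end <- af[, last]
    present[, r] <- !is.na(f_end) & f_end > 0
    if (d_g > 0) {
      f_start <- af[, first]
      ok <- !is.na(f_start) & !is.na(f_end)
      s_eff[ok, r] <- selection_coefficient(f_start[ok], f_end[ok], d_g,
                                            f_floor = f_floor)
    }
  }
  mean_s <- vapply(seq_len(n_sites(table)), function(i) {
    v <- s_eff[i, present[i, ]]
    if (all(is.na(v)) || !length(v)) NA_real_ else mean(v, na.rm = TRUE)
  }, 1)
  out <- data.frame(table$sites[, c("contig", "pos", "ref", "alt")],
                    n_replicates_present = as.integer(rowSums(present)),
                    mean_s_eff = mean_s,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(effects)) {
    stopifnot(length(effects) == n_sites(table))
    out$effect_class <- as.character(effects)
  }
  out
}

#' Two-sided Mann-Whitney U test
#'
#' Exact by complete enumeration of all label arrangements when
#' `n + m <= 12` (ties handled with mid-ranks; the two-sided p-value counts
#' arrangements whose U deviates from its null mean at least as much as the
#' observed one). Larger samples use the normal approximation with the tie
#' correction to the variance.
#'
#' @param x,y numeric vectors (non-empty).
#' @return two-sided p-value.
#' @export
mannwhitney_two_sided <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  mu <- n * m / 2
  if (N <= 12) {
    dev_obs <- abs(u_obs - mu)
    combos <- combn(N, n)
    devs <- abs(colSums(matrix(r[combos], nrow = n)) - n * (n + 1) / 2 - mu)
    return(mean(devs >= dev_obs - 1e-9))
  }
  ties <- table(r)
  sigma2 <- n * m / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  min(1, 2 * pnorm(-abs(u_obs - mu) / sqrt(sigma2)))
}

#' Two-sided Welch t test
#'
#' Unequal-variance t with Satterthwaite degrees of freedom. When both
#' groups are constant the statistic is undefined: equal means give p = 1,
#' different means p = 0 (with a warning).
#'
#' @param x,y numeric vectors with at least two values each.
#' @return two-sided p-value.
#' @export
welch_t_two_sided <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs n >= 2")
  vx <- var(x); vy <- var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) return(1)
    warning("both groups constant with different means; p = 0")
    return(0)
  }
  stats::t.test(x, y, var.equal = FALSE)$p.value
}

#' Wald test of a two-group Poisson log-linear model
#'
#' Models counts as Poisson with a log link and a group effect; the group
#' coefficient is `beta = ln(mean_b / mean_a)` with Wald standard error
#' `sqrt(1/sum(a) + 1/sum(b))` (identical to the `glm` Wald z test, since
#' the group totals are sufficient).
#'
#' @param counts_a,counts_b non-negative integer counts per group.
#' @return two-sided p-value.
#' @export
poisson_loglinear_two_group <- function(counts_a, counts_b) {
  stopifnot(all(counts_a >= 0), all(counts_b >= 0),
            length(counts_a) >= 1, length(counts_b) >= 1)
  ta <- sum(counts_a); tb <- sum(counts_b)
  if (ta == 0 || tb == 0)
    stop("a group total of 0 leaves the group coefficient unbounded")
  beta <- log(mean(counts_b) / mean(counts_a))
  se <- sqrt(1 / ta + 1 / tb)
  2 * pnorm(-abs(beta) / se)
}

#' Compare repeatability and frequency change between effect classes
#'
#' Tests whether synonymous and non-synonymous SNPs differ in (a) the
#' number of replicates in which they occur (Mann-Whitney on
#' `n_replicates_present`) and (b) mean frequency change (Welch t on
#' `mean_s_eff`). Intergenic and start/stop-codon changes are excluded:
#' predictions about their average fitness effects are less clear.
#'
#' @param records output of [repeatability()] with an `effect_class` column.
#' @return list with `p_repeatability` and `p_selection` (NA with a warning
#'   when a class has fewer than two records).
#' @export
class_comparison <- function(records) {
  if (is.null(records$effect_class))
    stop("records need an effect_class column")
  syn <- records[records$effect_class == "synonymous", , drop = FALSE]
  non <- records[records$effect_class == "nonsynonymous", , drop = FALSE]
  if (nrow(syn) < 2 || nrow(non) < 2) {
    warning("need >= 2 synonymous and >= 2 nonsynonymous records; ",
            "comparison undefined")
    return(list(p_repeatability = NA_real_, p_selection = NA_real_))
  }
  p_rep <- mannwhitney_two_sided(non$n_replicates_present,
                                 syn$n_replicates_present)
  s_non <- non$mean_s_eff[!is.na(non$mean_s_eff)]
  s_syn <- syn$mean_s_eff[!is.na(syn$mean_s_eff)]
  p_sel <- if (length(s_non) >= 2 && length(s_syn) >= 2)
    welch_t_two_sided(s_non, s_syn) else NA_real_
  list(p_repeatability = p_rep, p_selection = p_sel)
}
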
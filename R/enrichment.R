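#' Holm step-down family-wise error-rate adjustment
#'
#' `adjusted_(i) = max_{j <= i} min(1, (m - j + 1) * p_(j))` over the
#' ascending order, returned in input order (delegates to
#' [stats::p.adjust()]).
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in input order.
#' @export
holm_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "holm")
}

#' Per-ORF excess-variation scan (Fisher's exact test + Holm)
#'
#' For every ORF in the annotation, builds the 2x2 contingency table of
#' variable versus invariant sites inside versus outside the ORF:
#' `[[m_orf, L_orf - m_orf], [m_total - m_orf, L_G - L_orf - (m_total -
#' m_orf)]]`, and computes the one-sided enrichment p-value — the
#' hypergeometric upper tail `P(X >= m_orf)`, identical to a one-sided
#' Fisher's exact test. The question is "more mutations than expected
#' under a uniform genome-wide probability, given gene length", so only
#' the enrichment tail is relevant. The family of all ORFs tested is
#' Holm-corrected. A site falling in several overlapping ORFs counts for
#' each of them.
#'
#' @param snp_positions integer positions of the variable sites (one
#'   contig; duplicated positions are counted once).
#' @param annotation a [genome_annotation()]; every ORF is tested.
#' @param m_total genome-wide number of distinct variable sites; defaults
#'   to `length(unique(snp_positions))` but can be supplied when the scan
#'   runs on a subset of positions.
#' @param alpha family-wise error rate for the `significant` call.
#' @return data.frame with one row per ORF: `orf`, `start`, `end`,
#'   `length`, `m_orf`, `p_raw`, `p_holm`, `significant`.
#' @export
orf_scan <- function(snp_positions, annotation,
                     m_total = length(unique(snp_positions)), alpha = 0.05) {
  snp_positions <- unique(as.integer(snp_positions))
  L_G <- annotation$genome_length
  if (m_total > L_G) stop("m_total exceeds genome length")
  rows <- lapply(annotation$orfs, function(o) {
    inside <- vapply(seq_len(nrow(o$segments)), function(k) {
      sum(snp_positions >= o$segments[k, 1] & snp_positions <= o$segments[k, 2])
    }, 1L)
    m_orf <- sum(inside)
    if (m_orf > o$length) stop("more variable sites than positions in ORF ", o$name)
    data.frame(orf = o$name, start = min(o$segments[, 1]),
               end = max(o$segments[, 2]), length = o$length, m_orf = m_orf,
               p_raw = phyper(m_orf - 1, o$length, L_G - o$length, m_total,
                              lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out$p_holm <- holm_adjust(out$p_raw)
  out$significant <- out$p_holm < alpha
  out
}

#' Count SNP neighbors within a window
#'
#' For each focal SNP, the number of SNPs (including itself) within
#' `window` bp — the spatial-clustering summary used to visualize groups
#' of co-located variants.
#'
#' @param snp_positions integer positions on one contig.
#' @param window half-window in bp (default 500).
#' @return data.frame with `pos` and `count` (empty for empty input).
#' @export
neighbor_counts <- function(snp_positions, window = 500) {
  snp_positions <- as.integer(snp_positions)
  data.frame(pos = snp_positions,
             count = vapply(snp_positions, function(p) {
               sum(abs(snp_positions - p) <= window)
             }, 1L))
}
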
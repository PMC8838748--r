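# fixture builders shared across test files; all fixtures are generated in
# code, none are stored on disk

# a sample sheet with n_reps replicates sequenced at the given days, plus
# optional ancestor libraries; first half weak-, second half strong-demography
make_sheet <- function(n_reps = 6, days = c(12, 25, 38, 51, 64), n_anc = 0,
                       batch_by_treatment = TRUE) {
  treatments <- rep(c("weak_demography", "strong_demography"),
                    c(ceiling(n_reps / 2), floor(n_reps / 2)))
  rows <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
    data.frame(sample_id = sprintf("R%d_d%02d", r, days),
               replicate_id = paste0("R", r), treatment = treatments[r],
               day = days,
               batch_id = if (batch_by_treatment)
                 ifelse(treatments[r] == "weak_demography", "novaseq", "nextseq")
               else "batch1",
               stringsAsFactors = FALSE)
  }))
  if (n_anc > 0) {
    rows <- rbind(rows, data.frame(
      sample_id = sprintf("ANC_%d", seq_len(n_anc)), replicate_id = "ANC",
      treatment = "ancestor", day = NA_real_, batch_id = "nextseq",
      stringsAsFactors = FALSE))
  }
  sample_sheet(rows)
}

# deterministic variant table from a matrix of target allele frequencies:
# alt = round(af * depth); NA entries get depth below min_depth (missing)
table_from_af <- function(af, sheet, depth = 1000, qual = 1000,
                          min_depth = 10, pos = NULL) {
  af <- as.matrix(af)
  n <- nrow(af)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  sites <- data.frame(contig = "fix_1", pos = pos,
                      ref = "A", alt = "G", qual = qual,
                      stringsAsFactors = FALSE)
  dp <- matrix(depth, n, ncol(af))
  dp[is.na(af)] <- max(0L, min_depth - 1L)
  a <- round(ifelse(is.na(af), 0, af) * dp)
  variant_table(sites, sheet, dp - a, a, min_depth = min_depth)
}

# independent effect-classification oracle: rebuild the whole CDS before and
# after the mutation, translate both with Biostrings, and compare proteins
translate_oracle <- function(genome, pos, alt) {
  seqc <- strsplit(genome$sequence, "", fixed = TRUE)[[1]]
  covering <- Filter(function(o) {
    o$cds_ok && any(apply(o$segments, 1, function(sg) pos >= sg[1] && pos <= sg[2]))
  }, genome$orfs)
  if (!length(covering)) return("intergenic")
  best <- NULL; best_sev <- -1; best_start <- Inf
  sev <- c(intergenic = 0, synonymous = 1, nonsynonymous = 2,
           start_lost = 3, stop_gained = 3, stop_lost = 3)
  for (o in covering) {
    extract_cds <- function(chars) {
      parts <- unlist(lapply(seq_len(nrow(o$segments)), function(k) {
        chars[o$segments[k, 1]:o$segments[k, 2]]
      }))
      d <- Biostrings::DNAString(paste(parts, collapse = ""))
      if (o$strand == "-") d <- Biostrings::reverseComplement(d)
      d
    }
    mut <- seqc; mut[pos] <- alt
    prot_ref <- as.character(Biostrings::translate(extract_cds(seqc),
                                                   no.init.codon = TRUE))
    prot_alt <- as.character(Biostrings::translate(extract_cds(mut),
                                                   no.init.codon = TRUE))
    pr <- strsplit(prot_ref, "")[[1]]; pa <- strsplit(prot_alt, "")[[1]]
    diff <- which(pr != pa)
    cls <- if (!length(diff)) {
      "synonymous"
    } else {
      i <- diff[1]
      if (pr[i] != "*" && pa[i] == "*") "stop_gained"
      else if (pr[i] == "*" && pa[i] != "*") "stop_lost"
      else if (i == 1 && pr[1] == "M") "start_lost"
      else "nonsynonymous"
    }
    st <- o$segments[1, 1]
    if (sev[cls] > best_sev || (sev[cls] == best_sev && st < best_start)) {
      best <- cls; best_sev <- sev[cls]; best_start <- st
    }
  }
  best
}

# helper: key of site i
site_key_of <- function(vt, i) {
  paste(vt$sites$contig[i], vt$sites$pos[i], vt$sites$ref[i],
        vt$sites$alt[i], sep = ":")
}
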
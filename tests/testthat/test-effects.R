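toy9 <- function(seq = "ATGAAATAA", strand = "+") {
  genome_annotation("toy", nchar(seq), list(orf("g1", cbind(1, 9), strand)),
                    sequence = seq)
}

test_that("the codon classifier reproduces the standard genetic code cases", {
  g <- toy9()   # ATG AAA TAA on the plus strand
  expect_equal(classify_snp(list(pos = 6, alt = "G"), g), "synonymous")
  expect_equal(classify_snp(list(pos = 4, alt = "T"), g), "stop_gained")
  expect_equal(classify_snp(list(pos = 7, alt = "C"), g), "stop_lost")
  expect_equal(classify_snp(list(pos = 1, alt = "G"), g), "start_lost")
  expect_equal(classify_snp(list(pos = 5, alt = "G"), g), "nonsynonymous")

  # ref-base check is enforced
  expect_error(classify_snp(list(pos = 6, ref = "C", alt = "G"), g),
               "mismatch")

  # reverse-complement genome with a minus-strand ORF is the mirror case:
  # TTATTTCAT read leftwards is ATGAAATAA
  gm <- toy9("TTATTTCAT", strand = "-")
  expect_equal(classify_snp(list(pos = 4, alt = "C"), gm), "synonymous")
  expect_equal(classify_snp(list(pos = 9, alt = "C"), gm), "start_lost")

  # a site outside every ORF is intergenic
  g2 <- genome_annotation("toy", 12, list(orf("g1", cbind(1, 9), "+")),
                          sequence = "ATGAAATAAGGG")
  expect_equal(classify_snp(list(pos = 11, alt = "A"), g2), "intergenic")
})

test_that("classifier agrees with the whole-CDS translation oracle,
          exhaustively on small genomes", {
  for (seed in 1:4) {
    g <- make_toy_genome(400, seed = seed, n_orfs = 3, codon_range = c(5, 30))
    seqc <- strsplit(g$sequence, "", fixed = TRUE)[[1]]
    pos <- rep(seq_len(g$genome_length), each = 3)
    alt <- unlist(lapply(seqc, function(b) setdiff(c("A", "C", "G", "T"), b)))
    got <- classify_variants(data.frame(pos = pos, alt = alt), g)
    want <- vapply(seq_along(pos),
                   function(i) translate_oracle(g, pos[i], alt[i]), "")
    expect_equal(got, want)
  }
})

test_that("multi-segment ORFs map positions through the segment chain", {
  # CDS = [1..6] + [11..13]: ATG AAA | TAA with a 4-base insertion between
  g <- genome_annotation(
    "toy", 13, list(orf("g1", rbind(c(1, 6), c(11, 13)), "+")),
    sequence = "ATGAAACCCCTAA")
  expect_equal(classify_snp(list(pos = 6, alt = "G"), g), "synonymous")
  expect_equal(classify_snp(list(pos = 12, alt = "C"), g), "stop_lost")
  expect_equal(classify_snp(list(pos = 8, alt = "A"), g), "intergenic")
})

test_that("strand symmetry: classification is invariant under
          reverse-complementing the whole genome", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (seed in 5:7) {
    g <- make_toy_genome(300, seed = seed, n_orfs = 2, codon_range = c(5, 20))
    L <- g$genome_length
    seq_rc <- paste(rev(unname(comp[strsplit(g$sequence, "")[[1]]])),
                    collapse = "")
    orfs_rc <- lapply(g$orfs, function(o) {
      orf(o$name, cbind(L - o$segments[, 2] + 1L, L - o$segments[, 1] + 1L),
          if (o$strand == "+") "-" else "+")
    })
    g_rc <- genome_annotation("rc", L, orfs_rc, sequence = seq_rc)
    set.seed(seed)
    pos <- sample.int(L, 40)
    alt <- vapply(pos, function(p) {
      sample(setdiff(c("A", "C", "G", "T"),
                     substr(g$sequence, p, p)), 1)
    }, "")
    a <- classify_variants(data.frame(pos = pos, alt = alt), g)
    b <- classify_variants(data.frame(pos = L - pos + 1L,
                                      alt = unname(comp[alt])), g_rc)
    expect_equal(a, b)
  }
})

test_that("overlapping ORFs resolve by severity with a deterministic
          tie-break", {
  # two plus-strand ORFs sharing sequence; pos 13 G->C is synonymous for g1
  # (CTG->CTC, Leu) but nonsynonymous for g2 (GGG->GGC is Gly->Gly; pick a
  # change that differs): use pos 13 G->A: g1 CTG->CTA (Leu, synonymous),
  # g2 GAT codon... construct explicitly below
  s <- paste0("ATGCTG", "ATGGAT", "TAATAA", "TAG")  # g1: 1-18, g2: 7-21
  g <- genome_annotation(
    "toy", nchar(s),
    list(orf("g1", cbind(1, 18), "+"), orf("g2", cbind(7, 21), "+")),
    sequence = s)
  # pos 6 G->A: g1 codon2 CTG->CTA (synonymous); outside codon change for
  # g2? pos 6 < 7, g2 unaffected -> class synonymous
  expect_equal(classify_snp(list(pos = 6, alt = "A"), g), "synonymous")
  # pos 12 T->C: g1 codon4 GAT->GAC (synonymous, Asp); g2 codon2 GAT->GAC
  # also synonymous; tie -> class synonymous either way
  expect_equal(classify_snp(list(pos = 12, alt = "C"), g), "synonymous")
  # pos 11 A->G: g1 codon4 GAT->GGT nonsynonymous; g2 codon2 GAT->GGT
  # nonsynonymous; severity over any synonymous interpretation
  expect_equal(classify_snp(list(pos = 11, alt = "G"), g), "nonsynonymous")
  # pos 13 T->A: g1 codon5 TAA stop stays stop (TAA->AAA is stop_lost for
  # g1); g2 codon3 TAA->AAA stop_lost; highest severity wins
  expect_equal(classify_snp(list(pos = 13, alt = "A"), g), "stop_lost")
})

test_that("the exhaustive null spectrum enumerates 3L variants", {
  g <- toy9()
  spec <- null_spectrum(g, keep_variants = TRUE)
  expect_equal(spec$total, 27)
  v <- attr(spec, "variants")
  want <- vapply(seq_len(nrow(v)),
                 function(i) translate_oracle(g, v$pos[i], v$alt[i]), "")
  expect_equal(unname(spec$counts[names(table(want))]),
               unname(as.integer(table(want))))

  # no ORFs: everything intergenic
  g0 <- genome_annotation("toy", 10, list(),
                          sequence = paste(rep("A", 10), collapse = ""))
  s0 <- null_spectrum(g0)
  expect_equal(unname(s0$counts["intergenic"]), 30L)
  expect_equal(s0$total, 30)

  # totals conserve for random annotations
  for (seed in 8:9) {
    g <- make_toy_genome(250, seed = seed, n_orfs = 2, codon_range = c(4, 15))
    expect_equal(null_spectrum(g)$total, 3 * g$genome_length)
  }
})

test_that("spectrum test: proportional spectra give p = 1, gross distortion
          is detected, and seeds reproduce", {
  emp <- effect_spectrum(rep(c("synonymous", "nonsynonymous"), c(10, 30)))
  nul <- effect_spectrum(rep(c("synonymous", "nonsynonymous"), c(100, 300)))
  res <- spectrum_test(emp, nul, n_mc = 2000, seed = 3)
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 1)

  emp2 <- effect_spectrum(rep("synonymous", 100))
  nul2 <- effect_spectrum(rep(c("synonymous", "nonsynonymous"), c(50, 50)))
  res2 <- spectrum_test(emp2, nul2, n_mc = 10000, seed = 3)
  expect_lte(res2$p.value, 0.001)
  # cross-check against the exact hypergeometric tail on the 2x2 table
  exact <- fisher.test(rbind(c(100, 0), c(50, 50)))$p.value
  expect_lt(exact, 0.001)

  res3 <- spectrum_test(emp2, nul2, n_mc = 10000, seed = 3)
  expect_identical(res2$p.value, res3$p.value)
})

test_that("intergenic fraction is interval arithmetic over ORF segments", {
  g0 <- genome_annotation("t", 100, list())
  expect_equal(intergenic_fraction(g0), 1)
  g1 <- genome_annotation("t", 99, list(orf("aR", cbind(1, 99), "+")))
  expect_equal(intergenic_fraction(g1), 0)
  # 95% covered leaves 0.05
  g2 <- genome_annotation("t", 120, list(orf("aR", cbind(1, 114), "+")))
  expect_equal(intergenic_fraction(g2), 0.05)
})
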
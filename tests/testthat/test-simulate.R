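test_that("without mutation or selection nothing segregates", {
  cfg <- sim_config(L = 1000, mu = 0, n_generations = 20,
                    sample_generations = c(0, 20), N_max = 1000,
                    treatments = "weak_demography", n_replicates = 1,
                    seed = 1)
  r <- simulate_wf(cfg)$replicates[[1]]
  expect_equal(nrow(r$freq), 0)
  expect_equal(nrow(r$truth), 0)
})

test_that("deterministic-limit trajectories match the logistic closed form", {
  s <- 0.07; f0 <- 0.005
  cfg <- sim_config(L = 100, mu = 0, n_generations = 100,
                    sample_generations = 0:100, N_max = 1e6,
                    treatments = "weak_demography", n_replicates = 1,
                    selected_sites = setNames(s, "50"),
                    init_haplotypes = list(list(sites = 50, f0 = f0)),
                    deterministic = TRUE, seed = 2)
  f <- simulate_wf(cfg)$replicates[[1]]$freq[1, ]
  g <- 0:100
  closed <- f0 * exp(s * g) / (1 - f0 + f0 * exp(s * g))
  expect_lt(max(abs(f - closed)), 1e-10)
})

test_that("a neutral mutant at 1/N fixes with probability about 1/N", {
  n_runs <- 4000; N <- 100
  set.seed(11)
  seeds <- sample.int(2^31 - 1, n_runs)
  fixed <- vapply(seeds, function(sd) {
    cfg <- sim_config(L = 100, mu = 0, n_generations = 2000,
                      sample_generations = 2000, N_max = N,
                      treatments = "weak_demography", n_replicates = 1,
                      init_haplotypes = list(list(sites = 50, f0 = 1 / N)),
                      seed = sd)
    simulate_wf(cfg)$replicates[[1]]$freq[1, 1] >= 1
  }, TRUE)
  p_hat <- mean(fixed)
  se <- sqrt(0.01 * 0.99 / n_runs)
  expect_lt(abs(p_hat - 1 / N), 3 * se)
})

test_that("pooled sequencing has binomial noise around the truth and an
          error floor", {
  sheet <- make_sheet(1, 12)
  cfg <- sim_config(depth_mean = 1000, seq_error = 0, seed = 1)
  sites1 <- data.frame(contig = "s", pos = 1, ref = "A", alt = "G", qual = 1000)

  set.seed(21)
  vt0 <- sample_poolseq(matrix(0, 1, 1), cfg, sites1, sheet)
  expect_equal(unname(vt0$alt_count[1, 1]), 0L)

  # mean observed frequency over 1000 libraries tracks f = 0.5
  sheetN <- sample_sheet(data.frame(
    sample_id = paste0("S", 1:1000), replicate_id = "R1",
    treatment = "weak_demography", day = 12, batch_id = "b"))
  vt5 <- sample_poolseq(matrix(0.5, 1, 1000), cfg, sites1, sheetN)
  af5 <- allele_freq(vt5)
  se <- sqrt(0.25 / 1000) / sqrt(1000)
  expect_lt(abs(mean(af5) - 0.5), 3 * se + 1e-3)

  # symmetric sequencing error floors the observed frequency near e
  cfg_e <- sim_config(depth_mean = 1000, seq_error = 1e-3, seed = 1)
  vt_e <- sample_poolseq(matrix(0, 1, 1000), cfg_e, sites1, sheetN)
  expect_lt(abs(mean(allele_freq(vt_e)) - 1e-3), 5e-4)
})

test_that("artifact injection produces sites the matching filters flag", {
  sheet <- make_sheet(n_reps = 6, n_anc = 5)
  base <- subset_sites(table_from_af(matrix(0.5, 1, 35), sheet), integer(0))

  # zero artifacts requested: table unchanged
  cfg0 <- sim_config(seed = 1)
  expect_identical(inject_artifacts(base, cfg0)$table$sites, base$sites)

  # batch-wide artifacts at mid frequencies are always flagged
  set.seed(31)
  cfg_u <- sim_config(artifact_spec = list(n_constant = 0, n_ubiquitous = 30,
                                           ubiquitous_f_range = c(0.45, 0.55)),
                      seed = 1)
  tab_u <- inject_artifacts(base, cfg_u)$table
  expect_true(all(filter_ubiquitous_polymorphism(tab_u)))

  # constant artifacts are flagged by the binomial filter almost always
  set.seed(32)
  cfg_c <- sim_config(artifact_spec = list(n_constant = 200,
                                           constant_f_range = c(0.25, 0.35),
                                           n_ubiquitous = 0),
                      seed = 1)
  tab_c <- inject_artifacts(base, cfg_c)$table
  expect_gte(mean(filter_constant(tab_c)$flag), 0.95)
})

test_that("simulated experiments are byte-identical under one seed", {
  cfg <- sim_config(L = 5000, mu = 1e-6, n_generations = 30,
                    sample_generations = c(0, 15, 30), N_max = 2000,
                    n_replicates = 2,
                    treatments = c("weak_demography", "strong_demography"),
                    n_ancestors = 1,
                    artifact_spec = list(n_constant = 3,
                                         constant_f_range = c(0.2, 0.8),
                                         n_ubiquitous = 3,
                                         ubiquitous_f_range = c(0.2, 0.8)),
                    seed = 99)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$table$alt_count, b$table$alt_count)
  expect_identical(a$truth, b$truth)
  fa <- tempfile(); fb <- tempfile()
  write_variant_table(a$table, fa, "vcf")
  write_variant_table(b$table, fb, "vcf")
  expect_identical(readLines(fa), readLines(fb))
})

test_that("de novo mutations appear under positive mutation supply with
          truth labels", {
  cfg <- sim_config(L = 10000, mu = 1e-7, n_generations = 40,
                    sample_generations = c(0, 40), N_max = 5000,
                    treatments = "weak_demography", n_replicates = 1,
                    n_ancestors = 0, seed = 12)
  sim <- simulate_experiment(cfg)
  expect_gt(nrow(sim$truth), 0)
  expect_true(all(sim$truth$label == "neutral"))
  wf <- simulate_wf(cfg)$replicates[[1]]
  expect_true(all(wf$truth$origin_gen > 0))
})

test_that("bottlenecks erode diversity relative to constant size", {
  # ten neutral haplotypes at 10% each; strong demography crashes to N_min
  n_pairs <- 20
  init <- lapply(1:10, function(i) list(sites = i * 10, f0 = 0.1))
  endpoint_pi <- function(treatment, sd) {
    cfg <- sim_config(L = 1000, mu = 0, n_generations = 75,
                      sample_generations = 75, N_max = 1e4, N_min = 10,
                      treatments = treatment, n_replicates = 1,
                      init_haplotypes = init, seed = sd)
    f <- simulate_wf(cfg)$replicates[[1]]$freq[, 1]
    sum(2 * f * (1 - f))
  }
  set.seed(55)
  seeds <- sample.int(2^31 - 1, n_pairs)
  lower <- vapply(seeds, function(sd) {
    endpoint_pi("strong_demography", sd) < endpoint_pi("weak_demography", sd)
  }, TRUE)
  # sign test: bottlenecked replicates end less diverse than constant ones
  expect_lt(binom.test(sum(lower), n_pairs, 0.5,
                       alternative = "greater")$p.value, 0.05)
})

test_that("toy genomes honor ORF grammar at small and genome scale", {
  g <- make_toy_genome(9, data.frame(start = 1, end = 9, strand = "+"),
                       seed = 5)
  expect_equal(substr(g$sequence, 1, 3), "ATG")
  expect_true(substr(g$sequence, 7, 9) %in% c("TAA", "TAG", "TGA"))

  g0 <- make_toy_genome(50, seed = 5)
  expect_equal(nchar(g0$sequence), 50)
  expect_length(g0$orfs, 0)

  expect_error(make_toy_genome(30, data.frame(start = c(1, 7),
                                              end = c(9, 15),
                                              strand = "+"), seed = 1),
               "overlap")
  expect_error(make_toy_genome(30, data.frame(start = 1, end = 10,
                                              strand = "+"), seed = 1),
               "multiples of 3")

  # full experimental scale: 812 ORFs in a 330,611 bp genome validate
  big <- make_toy_genome(330611, seed = 6, n_orfs = 812)
  expect_length(big$orfs, 812)
  expect_equal(nchar(big$sequence), 330611)
  # every ORF starts with ATG and ends with a stop on its own strand
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ok <- vapply(big$orfs, function(o) {
    cds <- substr(big$sequence, o$segments[1, 1], o$segments[1, 2])
    if (o$strand == "-") {
      cds <- paste(rev(unname(comp[strsplit(cds, "")[[1]]])), collapse = "")
    }
    substr(cds, 1, 3) == "ATG" &&
      substr(cds, nchar(cds) - 2, nchar(cds)) %in% c("TAA", "TAG", "TGA")
  }, TRUE)
  expect_true(all(ok))
})
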
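STOP_CODONS <- c("TAA", "TAG", "TGA")

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' Simulation configuration
#'
#' Parameters of the clonal Wright-Fisher / pooled-sequencing generator.
#' Defaults emulate the statistical structure of a replicated
#' Chlorovirus-Chlorella chemostat coevolution experiment: a ~330 kb
#' clonal dsDNA genome, 2e-8 mutations per site per replication event, six
#' replicates sampled at five time points over ~75 generations (days 12 to
#' 64), mean pooled coverage 1000x, and two demographic regimes — constant
#' size (weak demography) versus periodic crashes (strong demography).
#' The population is simulated at a desk-scale effective size (default
#' 1e5) rather than the experimental census ~1e10; at such large sizes the
#' frequency dynamics of selected alleles are essentially deterministic,
#' so the statistical structure is preserved (a deterministic-limit mode
#' is also available).
#'
#' @param L genome length in bp.
#' @param mu mutation rate per site per replication event.
#' @param n_generations total generations simulated.
#' @param sample_generations generations at which populations are pooled
#'   and sequenced (must include values in `[0, n_generations]`).
#' @param N_max population size (constant regime) / pre-crash size.
#' @param N_min size at a bottleneck (default `N_max * crash_factor`).
#' @param crash_factor,bottleneck_period strong-demography stylization: the
#'   population crashes to `N_max * crash_factor` every
#'   `bottleneck_period` generations.
#' @param treatments character vector, one per replicate, each
#'   `"weak_demography"` (constant N) or `"strong_demography"` (periodic
#'   crashes).
#' @param selected_sites named numeric vector mapping genomic position to
#'   selection coefficient `s`; class fitness is `exp(sum(s))` over carried
#'   mutations (log-additive), so a lineage with coefficient `s` grows by
#'   a factor `e^s` per generation relative to the mean.
#' @param init_haplotypes list of `list(sites = <positions>, f0 =
#'   <frequency>, replicate = <index or NULL for all>)`: founding
#'   haplotypes present at generation 0, used to inject variants without
#'   waiting for mutation.
#' @param depth_mean mean pooled sequencing depth (Poisson).
#' @param seq_error per-read sequencing error rate (applied symmetrically).
#' @param n_replicates number of evolutionary replicates.
#' @param n_ancestors number of ancestor (generation-0 isogenic) libraries.
#' @param day0 experiment day of generation 0 (virus addition).
#' @param days_per_gen days per generation used to place sampling days
#'   (default 52/75).
#' @param batch_map named character vector mapping treatment to sequencing
#'   batch id.
#' @param artifact_spec list with `n_constant`, `constant_f_range`,
#'   `n_ubiquitous`, `ubiquitous_f_range` controlling injected artifact
#'   variants.
#' @param qual caller quality assigned to simulated sites.
#' @param deterministic use the infinite-population deterministic limit
#'   (requires `mu = 0`).
#' @param class_cap guard on the number of tracked genotype classes.
#' @param seed integer seed; mandatory for reproducible output.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(L = 330611, mu = 2e-8, n_generations = 75,
                       sample_generations = c(0, 19, 38, 56, 75),
                       N_max = 1e5, N_min = NULL, crash_factor = 1e-3,
                       bottleneck_period = 15,
                       treatments = rep(c("weak_demography",
                                          "strong_demography"), each = 3),
                       selected_sites = NULL, init_haplotypes = NULL,
                       depth_mean = 1000, seq_error = 1e-3,
                       n_replicates = length(treatments), n_ancestors = 5,
                       day0 = 12, days_per_gen = 52 / 75,
                       batch_map = c(weak_demography = "novaseq_s1",
                                     strong_demography = "nextseq",
                                     ancestor = "nextseq"),
                       artifact_spec = list(n_constant = 0,
                                            constant_f_range = c(0.1, 0.9),
                                            n_ubiquitous = 0,
                                            ubiquitous_f_range = c(0.1, 0.9)),
                       qual = 1000, deterministic = FALSE,
                       class_cap = 20000, seed = NULL) {
  if (is.null(N_min)) N_min <- max(2, round(N_max * crash_factor))
  stopifnot(mu >= 0, mu <= 1, L >= 1, N_min <= N_max,
            all(sample_generations >= 0),
            all(sample_generations <= n_generations))
  if (length(treatments) != n_replicates)
    treatments <- rep_len(treatments, n_replicates)
  stopifnot(all(treatments %in% c("weak_demography", "strong_demography")))
  if (deterministic && mu > 0)
    stop("deterministic mode requires mu = 0")
  if (!is.null(selected_sites) && is.null(names(selected_sites)))
    stop("selected_sites must be a named vector (names = positions)")
  structure(list(L = as.integer(L), mu = mu, n_generations = n_generations,
                 sample_generations = sort(unique(sample_generations)),
                 N_max = N_max, N_min = N_min,
                 bottleneck_period = bottleneck_period,
                 treatments = treatments, selected_sites = selected_sites,
                 init_haplotypes = init_haplotypes, depth_mean = depth_mean,
                 seq_error = seq_error, n_replicates = n_replicates,
                 n_ancestors = n_ancestors, day0 = day0,
                 days_per_gen = days_per_gen, batch_map = batch_map,
                 artifact_spec = artifact_spec, qual = qual,
                 deterministic = deterministic, class_cap = class_cap,
                 seed = seed),
            class = "sim_config")
}

# population size at generation g under a treatment
pop_size_at <- function(cfg, treatment, g) {
  if (treatment == "strong_demography" && g > 0 &&
      g %% cfg$bottleneck_period == 0) cfg$N_min else cfg$N_max
}

# one clonal Wright-Fisher population; RNG state is the caller's
wf_population <- function(cfg, treatment, replicate_index) {
  sel <- cfg$selected_sites
  reg_pos <- integer(0); reg_s <- numeric(0); reg_origin <- integer(0)
  register_site <- function(pos) {
    s <- if (!is.null(sel) && as.character(pos) %in% names(sel))
      unname(sel[as.character(pos)]) else 0
    reg_pos <<- c(reg_pos, as.integer(pos))
    reg_s <<- c(reg_s, s)
    length(reg_pos)
  }
  N0 <- pop_size_at(cfg, treatment, 0)
  # isogenic start; deterministic mode tracks frequencies instead of counts
  cnt <- if (cfg$deterministic) 1 else N0
  w <- 1; mem <- list(integer(0))
  if (!is.null(cfg$init_haplotypes)) {
    for (h in cfg$init_haplotypes) {
      if (!is.null(h$replicate) && !replicate_index %in% h$replicate) next
      ids <- vapply(h$sites, function(p) {
        hit <- match(as.integer(p), reg_pos)
        if (is.na(hit)) register_site(p) else hit
      }, 1L)
      k <- if (cfg$deterministic) h$f0 else max(1, round(N0 * h$f0))
      cnt[1] <- cnt[1] - k
      cnt <- c(cnt, k)
      w <- c(w, exp(sum(reg_s[ids])))
      mem[[length(mem) + 1L]] <- ids
    }
    if (cnt[1] < 0) stop("init_haplotypes frequencies exceed 1")
  }
  reg_origin <- rep(0L, length(reg_pos))
  n_sample <- length(cfg$sample_generations)
  samples <- vector("list", n_sample)
  take_sample <- function(slot) {
    tot <- sum(cnt)
    freq <- numeric(length(reg_pos))
    for (j in seq_along(cnt)) {
      if (length(mem[[j]])) freq[mem[[j]]] <- freq[mem[[j]]] + cnt[j]
    }
    samples[[slot]] <<- freq / tot
  }
  slot <- 1L
  if (cfg$sample_generations[1] == 0) { take_sample(1L); slot <- 2L }
  for (g in seq_len(cfg$n_generations)) {
    N <- pop_size_at(cfg, treatment, g)
    probs <- cnt * w
    if (cfg$deterministic) {
      cnt <- probs / sum(probs)
    } else {
      cnt <- as.vector(rmultinom(1, N, probs))
    }
    keep <- cnt > 0
    if (!all(keep)) { cnt <- cnt[keep]; w <- w[keep]; mem <- mem[keep] }
    if (cfg$mu > 0) {
      n_mut <- rpois(1, N * cfg$mu * cfg$L)
      for (k in seq_len(n_mut)) {
        if (length(cnt) >= cfg$class_cap) {
          message("class cap reached; further mutations this generation dropped")
          break
        }
        parent <- sample.int(length(cnt), 1, prob = cnt)
        if (cnt[parent] < 1) next
        pos <- sample.int(cfg$L, 1)
        while (pos %in% reg_pos) pos <- sample.int(cfg$L, 1)
        id <- register_site(pos)
        reg_origin <- c(reg_origin, g)
        cnt[parent] <- cnt[parent] - 1
        cnt <- c(cnt, 1)
        mem[[length(mem) + 1L]] <- c(mem[[parent]], id)
        w <- c(w, exp(sum(reg_s[mem[[length(mem)]]])))
        if (cnt[parent] == 0) {
          keep <- cnt > 0
          cnt <- cnt[keep]; w <- w[keep]; mem <- mem[keep]
        }
      }
    }
    while (slot <= n_sample && cfg$sample_generations[slot] == g) {
      take_sample(slot); slot <- slot + 1L
    }
    if (cfg$mu == 0 && length(cnt) == 1L) {
      while (slot <= n_sample) { take_sample(slot); slot <- slot + 1L }
      break
    }
  }
  freq <- matrix(0, nrow = length(reg_pos), ncol = n_sample,
                 dimnames = list(reg_pos, cfg$sample_generations))
  for (j in seq_len(n_sample)) {
    f <- samples[[j]]
    if (length(f)) freq[seq_along(f), j] <- f
  }
  list(freq = freq,
       truth = data.frame(pos = reg_pos, s = reg_s, origin_gen = reg_origin,
                          stringsAsFactors = FALSE))
}

#' Simulate clonal Wright-Fisher evolution
#'
#' Genotype-class Wright-Fisher dynamics without recombination: the
#' population starts isogenic; each genotype class has fitness
#' `exp(sum(s))` over the mutations it carries; class counts in the next
#' generation are multinomial with probabilities proportional to
#' `count * fitness` at the generation's population size; new mutations
#' arrive as `Poisson(N * mu * L)`, each at a uniformly drawn unused site,
#' attached to a parent class drawn by frequency. Site frequencies are
#' derived from the class composition. Fully reproducible from the seed.
#'
#' @param cfg a [sim_config()] (its `seed` must be set).
#' @return list with `replicates` (per replicate: `freq`, a sites x
#'   sampled-generations frequency matrix with positions as rownames, and
#'   `truth`, per-site selection coefficient and origin generation) and
#'   `config`.
#' @export
simulate_wf <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$seed)) stop("cfg$seed must be set for reproducible runs")
  set.seed(cfg$seed)
  reps <- lapply(seq_len(cfg$n_replicates), function(r) {
    wf_population(cfg, cfg$treatments[r], r)
  })
  names(reps) <- paste0("R", seq_len(cfg$n_replicates))
  list(replicates = reps, config = cfg)
}

#' Pooled sequencing of true allele frequencies
#'
#' Per (site, sample): depth is `Poisson(depth_mean)` and the alternative
#' read count `Binomial(depth, f (1 - e) + (1 - f) e)` with symmetric
#' sequencing error `e`. Simulated sites receive the configured caller
#' quality. Uses the current RNG state (seed upstream).
#'
#' @param true_afs numeric matrix, sites x samples, of true frequencies.
#' @param cfg a [sim_config()] (uses `depth_mean`, `seq_error`, `qual`).
#' @param sites data.frame with `contig`, `pos`, `ref`, `alt` (and
#'   optionally `qual`), one row per row of `true_afs`.
#' @param samples a [sample_sheet()], one row per column of `true_afs`.
#' @param min_depth minimum depth for a frequency estimate in the
#'   resulting table.
#' @return a [variant_table()]
#' @export
sample_poolseq <- function(true_afs, cfg, sites, samples, min_depth = 10) {
  true_afs <- as.matrix(true_afs)
  stopifnot(all(true_afs >= 0 & true_afs <= 1),
            nrow(true_afs) == nrow(sites))
  n <- length(true_afs)
  dp <- matrix(rpois(n, cfg$depth_mean), nrow = nrow(true_afs))
  p <- true_afs * (1 - cfg$seq_error) + (1 - true_afs) * cfg$seq_error
  alt <- matrix(rbinom(n, as.vector(dp), as.vector(p)), nrow = nrow(true_afs))
  sites <- as.data.frame(sites)
  if (is.null(sites$qual)) sites$qual <- cfg$qual
  variant_table(sites, samples, dp - alt, alt, min_depth = min_depth)
}

# random ref/alt base pair per position
random_site_bases <- function(n) {
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1), "")
  data.frame(ref = ref, alt = unname(alt), stringsAsFactors = FALSE)
}

#' Simulate a full pooled-sequencing experiment
#'
#' Runs [simulate_wf()] for every replicate, pools each sampled
#' generation with [sample_poolseq()], adds isogenic ancestor libraries,
#' and injects artifact variants per the configuration's `artifact_spec`.
#' Sampling days are placed as `day0 + round(g * days_per_gen)`.
#'
#' @param cfg a [sim_config()] with `seed` set.
#' @return list with `table` (a [variant_table()]), `samples` (the sample
#'   sheet), `truth` (per site: position, ref/alt, label `real_sweep` /
#'   `neutral` / `artifact_constant` / `artifact_ubiquitous`, selection
#'   coefficient), `trajectories` (per-replicate true frequency matrices)
#'   and `config`.
#' @export
simulate_experiment <- function(cfg) {
  wf <- simulate_wf(cfg)     # seeds the RNG; later draws continue the stream
  gens <- cfg$sample_generations
  days <- cfg$day0 + round(gens * cfg$days_per_gen)
  rep_ids <- names(wf$replicates)

  sheet <- do.call(rbind, lapply(seq_along(rep_ids), function(r) {
    data.frame(sample_id = sprintf("%s_d%02d", rep_ids[r], days),
               replicate_id = rep_ids[r], treatment = cfg$treatments[r],
               day = days,
               batch_id = unname(cfg$batch_map[cfg$treatments[r]]),
               stringsAsFactors = FALSE)
  }))
  if (cfg$n_ancestors > 0) {
    sheet <- rbind(sheet, data.frame(
      sample_id = sprintf("ANC_%d", seq_len(cfg$n_ancestors)),
      replicate_id = "ANC", treatment = "ancestor", day = NA_real_,
      batch_id = unname(cfg$batch_map["ancestor"]),
      stringsAsFactors = FALSE))
  }
  sheet <- sample_sheet(sheet)

  # union of positions that ever segregate, plus declared selected sites
  pos_union <- sort(unique(c(
    unlist(lapply(wf$replicates, function(x) x$truth$pos[rowSums(x$freq) > 0])),
    as.integer(names(cfg$selected_sites)),
    unlist(lapply(cfg$init_haplotypes, `[[`, "sites")))))
  pos_union <- as.integer(pos_union)

  true_afs <- matrix(0, length(pos_union), nrow(sheet),
                     dimnames = list(pos_union, sheet$sample_id))
  s_vec <- numeric(length(pos_union))
  for (r in seq_along(rep_ids)) {
    x <- wf$replicates[[r]]
    hit <- match(x$truth$pos, pos_union)
    ok <- !is.na(hit)
    cols <- which(sheet$replicate_id == rep_ids[r])
    true_afs[hit[ok], cols] <- x$freq[ok, , drop = FALSE]
    s_vec[hit[ok]] <- x$truth$s[ok]
  }

  bases <- random_site_bases(length(pos_union))
  sites <- data.frame(contig = "sim_1", pos = pos_union,
                      ref = bases$ref, alt = bases$alt, qual = cfg$qual,
                      stringsAsFactors = FALSE)
  table <- sample_poolseq(true_afs, cfg, sites, sheet)
  truth <- data.frame(sites[, c("contig", "pos", "ref", "alt")],
                      label = ifelse(s_vec > 0, "real_sweep", "neutral"),
                      s = s_vec, stringsAsFactors = FALSE)
  out <- inject_artifacts(table, cfg, truth)
  list(table = out$table, samples = sheet, truth = out$truth,
       trajectories = lapply(wf$replicates, `[[`, "freq"), config = cfg)
}

#' Inject artifact variants into a variant table
#'
#' Adds the two artifact types the filter cascade is designed to remove:
#' `artifact_constant` sites have one constant latent frequency per
#' replicate (read counts binomial around it at every time point) —
#' mimicking mapping artifacts whose apparent frequency never changes; and
#' `artifact_ubiquitous` sites have one latent mid-range frequency shared
#' by every library of a sequencing batch — mimicking spurious
#' polymorphism from duplicated or complex regions. Artifact positions
#' colliding with existing sites are resampled. Uses the current RNG
#' state.
#'
#' @param table a [variant_table()]
#' @param cfg a [sim_config()] (uses `artifact_spec`, `depth_mean`, `L`,
#'   `qual`).
#' @param truth optional truth data.frame to extend (as produced by
#'   [simulate_experiment()]).
#' @return list with the augmented `table` and `truth`.
#' @export
inject_artifacts <- function(table, cfg, truth = NULL) {
  spec <- cfg$artifact_spec
  n_con <- spec$n_constant %||% 0
  n_ubi <- spec$n_ubiquitous %||% 0
  if (n_con + n_ubi == 0) return(list(table = table, truth = truth))
  used <- table$sites$pos
  draw_pos <- function(n) {
    out <- integer(0)
    while (length(out) < n) {
      cand <- sample.int(cfg$L, n - length(out))
      cand <- setdiff(cand, c(used, out))
      out <- c(out, cand)
    }
    used <<- c(used, out)
    out
  }
  smp <- table$samples
  n_s <- nrow(smp)
  make_rows <- function(n, latent_by) {
    pos <- draw_pos(n)
    bases <- random_site_bases(n)
    ref <- alt <- matrix(0L, n, n_s)
    groups <- split(seq_len(n_s), latent_by)
    rng <- if (identical(latent_by, smp$batch_id)) spec$ubiquitous_f_range
           else spec$constant_f_range
    for (g in groups) {
      f <- runif(n, rng[1], rng[2])          # one latent frequency per group
      dp <- matrix(rpois(n * length(g), cfg$depth_mean), n)
      a <- matrix(rbinom(n * length(g), as.vector(dp), rep(f, length(g))), n)
      alt[, g] <- a
      ref[, g] <- dp - a
    }
    list(sites = data.frame(contig = table$sites$contig[1] %||% "sim_1",
                            pos = pos, ref = bases$ref, alt = bases$alt,
                            qual = cfg$qual, stringsAsFactors = FALSE),
         ref = ref, alt = alt)
  }
  new_sites <- list(); new_ref <- list(); new_alt <- list(); labels <- character(0)
  if (n_con > 0) {
    r <- make_rows(n_con, smp$replicate_id)
    new_sites[[1]] <- r$sites; new_ref[[1]] <- r$ref; new_alt[[1]] <- r$alt
    labels <- c(labels, rep("artifact_constant", n_con))
  }
  if (n_ubi > 0) {
    r <- make_rows(n_ubi, smp$batch_id)
    new_sites[[length(new_sites) + 1L]] <- r$sites
    new_ref[[length(new_ref) + 1L]] <- r$ref
    new_alt[[length(new_alt) + 1L]] <- r$alt
    labels <- c(labels, rep("artifact_ubiquitous", n_ubi))
  }
  add_sites <- do.call(rbind, new_sites)
  table2 <- variant_table(rbind(table$sites, add_sites), smp,
                          rbind(table$ref_count, do.call(rbind, new_ref)),
                          rbind(table$alt_count, do.call(rbind, new_alt)),
                          min_depth = table$min_depth)
  if (!is.null(truth)) {
    truth <- rbind(truth,
                   data.frame(add_sites[, c("contig", "pos", "ref", "alt")],
                              label = labels, s = 0, stringsAsFactors = FALSE))
  }
  list(table = table2, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The standard benchmark scenario
#'
#' The package's reference simulation for exercising the filter cascade:
#' six replicates (three weak-, three strong-demography), five time points
#' at 1000x coverage, 20 genuine selective sweeps (per replicate, one
#' founding beneficial haplotype carrying a subset of the sweep sites at
#' starting frequency 1e-3 with s = 0.1 per site; each site is carried in
#' two replicates), 20 constant-frequency artifacts and 20 batch-wide
#' polymorphic artifacts.
#'
#' @param seed integer seed.
#' @return the [simulate_experiment()] result list.
#' @export
standard_scenario <- function(seed) {
  set.seed(seed)
  sweep_pos <- sort(sample.int(330611, 20))
  s <- setNames(rep(0.1, 20), sweep_pos)
  # site i rides the founding haplotype of replicates (i mod 6)+1 and (i+1 mod 6)+1
  haps <- lapply(1:6, function(r) {
    carried <- sweep_pos[(seq_len(20) - 1L) %% 6L + 1L == r |
                         seq_len(20) %% 6L + 1L == r]
    list(sites = carried, f0 = 1e-3, replicate = r)
  })
  cfg <- sim_config(mu = 0, selected_sites = s, init_haplotypes = haps,
                    artifact_spec = list(n_constant = 20,
                                         constant_f_range = c(0.1, 0.9),
                                         n_ubiquitous = 20,
                                         ubiquitous_f_range = c(0.1, 0.9)),
                    seed = seed)
  simulate_experiment(cfg)
}

#' Generate a toy genome with valid ORFs
#'
#' Builds a random reference sequence in which every requested ORF is a
#' syntactically valid CDS on its strand: it starts with ATG, ends with a
#' stop codon, and its internal codons are drawn from the 61 sense codons
#' only (so no premature stop can occur). ORFs must not overlap and their
#' lengths must be multiples of 3.
#'
#' @param L genome length in bp.
#' @param orf_spec data.frame with columns `start`, `end`, `strand` and
#'   optionally `name`; or `NULL` to place `n_orfs` random non-overlapping
#'   ORFs.
#' @param seed integer seed.
#' @param n_orfs number of random ORFs when `orf_spec` is `NULL`.
#' @param codon_range min/max number of codons for random ORFs.
#' @param contig contig name.
#' @return a [genome_annotation()] with sequence.
#' @export
make_toy_genome <- function(L, orf_spec = NULL, seed = 1, n_orfs = 0,
                            codon_range = c(10, 150), contig = "toy_1") {
  set.seed(seed)
  sense <- sense_codons()
  if (is.null(orf_spec)) {
    orf_spec <- data.frame(start = integer(0), end = integer(0),
                           strand = character(0))
    pos <- 1L
    for (i in seq_len(n_orfs)) {
      gap <- sample(5:40, 1)
      len <- 3L * sample(codon_range[1]:codon_range[2], 1)
      start <- pos + gap
      if (start + len - 1L > L)
        stop("could not place ", n_orfs, " ORFs in ", L, " bp")
      orf_spec <- rbind(orf_spec, data.frame(
        start = start, end = start + len - 1L,
        strand = sample(c("+", "-"), 1)))
      pos <- start + len
    }
  }
  orf_spec <- as.data.frame(orf_spec)
  if (is.null(orf_spec$name))
    orf_spec$name <- sprintf("orf%04d%s", seq_len(nrow(orf_spec)),
                             ifelse(orf_spec$strand == "+", "R", "L"))
  o <- order(orf_spec$start)
  orf_spec <- orf_spec[o, , drop = FALSE]
  if (nrow(orf_spec) > 1 &&
      any(orf_spec$start[-1] <= orf_spec$end[-nrow(orf_spec)]))
    stop("overlapping ORFs are not supported by the toy-genome generator")
  lens <- orf_spec$end - orf_spec$start + 1L
  if (any(lens %% 3L != 0L)) stop("ORF lengths must be multiples of 3")
  if (any(orf_spec$start < 1L) || any(orf_spec$end > L))
    stop("ORF outside [1, L]")

  seqc <- sample(BASES, L, replace = TRUE)
  orfs <- vector("list", nrow(orf_spec))
  for (i in seq_len(nrow(orf_spec))) {
    k <- lens[i] / 3L
    codons <- c("ATG",
                if (k > 2) sample(sense, k - 2, replace = TRUE),
                sample(STOP_CODONS, 1))
    cds <- strsplit(paste(codons, collapse = ""), "")[[1]]
    if (orf_spec$strand[i] == "-")
      cds <- rev(unname(COMPLEMENT[cds]))
    seqc[orf_spec$start[i]:orf_spec$end[i]] <- cds
    orfs[[i]] <- orf(orf_spec$name[i],
                     cbind(orf_spec$start[i], orf_spec$end[i]),
                     orf_spec$strand[i])
  }
  genome_annotation(contig, L, orfs, sequence = paste(seqc, collapse = ""))
}
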
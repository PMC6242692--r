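#' Configuration for the synthetic screen simulator
#'
#' Generates bacterial-genome-like data with the statistical structure the
#' pipeline assumes: operons with polar silencing, strand-dependent repression
#' (strong on the coding strand, weak on the template strand except for
#' "sensitive" genes), essential / near-essential fitness costs accumulating
#' over generations of growth, toxic bad-seed guides, phage screens where
#' silencing a host factor protects from lysis, and a transduction screen
#' where packaged-cosmid output depends jointly on guide fitness and
#' capsid-competence genes.
#'
#' Defaults describe the reference study conditions: 17 generations of growth,
#' 200 genes, an 8,000-guide library, 3 paired replicates at a sequencing
#' depth of 1e6 reads per sample. Effect sizes are set so that full silencing
#' of an essential gene over 17 generations yields a log2 fold-change near -7.
#'
#' @param seed Integer seed; mandatory. All randomness in the simulator flows
#'   from it (each stage derives its own sub-seed so stages are individually
#'   reproducible).
#' @param genome_length Genome size in nt (default 200000).
#' @param n_genes Number of genes (default 200).
#' @param tu_mean_size Mean transcription-unit size; TU sizes are
#'   1 + geometric (default 2).
#' @param fraction_essential,fraction_near_essential Marginal probabilities of
#'   the essentiality labels (defaults 0.2 and 0.1).
#' @param fraction_sensitive Fraction of essential genes intolerant even to
#'   the weak repression obtained on the template strand (default 0.1).
#' @param coding_effect_mean,coding_effect_sd Per-generation log2 fitness cost
#'   of fully silencing an essential gene (default normal(-0.4, 0.1)).
#' @param near_effect_mean,near_effect_sd Same for near-essential (slow
#'   growth) genes (default normal(-0.15, 0.05)).
#' @param template_effect_scale Scaling of the silencing effect for
#'   template-strand guides on non-sensitive genes (default 0.1).
#' @param repression_alpha,repression_beta Beta-distribution parameters for
#'   the per-guide repression efficiency (default Beta(9, 1), mean 0.9).
#' @param generations Generations of growth between the before and after
#'   samples of the growth screen (default 17).
#' @param polar Does silencing propagate to all downstream genes of the TU?
#'   (default `TRUE`).
#' @param bad_seed_penalty Per-generation fitness cost added to guides
#'   carrying a toxic seed (default -0.1).
#' @param library_size Number of genomic guides (default 8000; the
#'   non-targeting control guide is appended on top).
#' @param depth Reads per sample before overdispersion (default 1e6).
#' @param n_replicates Paired before/after replicates (default 3).
#' @param dispersion Negative-binomial overdispersion of counts (default 0.05;
#'   0 gives pure multinomial sampling).
#' @param abundance_sdlog Log-normal spread of initial guide abundances
#'   (default 0.5).
#' @param gene_length_mean,gene_length_sd Gene length distribution (defaults
#'   900, 200; floored at 300).
#' @param n_host_factors Genes whose silencing protects from phage lysis
#'   (default 10, drawn among non-essential genes).
#' @param protection_effect Survival fraction of cells carrying a protecting
#'   guide (default 0.9).
#' @param survival_floor Survival fraction of unprotected cells (default
#'   0.05).
#' @param n_capsid_genes Genes required for functional capsid production
#'   (default 10, disjoint from host factors, non-essential).
#' @param packaging_penalty log2 reduction of packaged-cosmid output when a
#'   capsid gene is silenced (default -3).
#' @param pregrowth_generations Generations of growth with dCas9 induced
#'   before infection; growth effects transfer into the phage and transduction
#'   "before" samples at this exposure (default 17, growth to stationary
#'   phase).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       genome_length = 200000L,
                       n_genes = 200L,
                       tu_mean_size = 2,
                       fraction_essential = 0.2,
                       fraction_near_essential = 0.1,
                       fraction_sensitive = 0.1,
                       coding_effect_mean = -0.4,
                       coding_effect_sd = 0.1,
                       near_effect_mean = -0.15,
                       near_effect_sd = 0.05,
                       template_effect_scale = 0.1,
                       repression_alpha = 9,
                       repression_beta = 1,
                       generations = 17,
                       polar = TRUE,
                       bad_seed_penalty = -0.1,
                       library_size = 8000L,
                       depth = 1e6,
                       n_replicates = 3L,
                       dispersion = 0.05,
                       abundance_sdlog = 0.5,
                       gene_length_mean = 900,
                       gene_length_sd = 200,
                       n_host_factors = 10L,
                       protection_effect = 0.9,
                       survival_floor = 0.05,
                       n_capsid_genes = 10L,
                       packaging_penalty = -3,
                       pregrowth_generations = 17) {
  if (missing(seed) || is.null(seed)) abort("`seed` is mandatory.")
  fr <- c(fraction_essential, fraction_near_essential, fraction_sensitive)
  if (any(fr < 0 | fr > 1)) abort("Fractions must lie in [0, 1].")
  if (fraction_essential + fraction_near_essential > 1) {
    abort("fraction_essential + fraction_near_essential must not exceed 1.")
  }
  if (depth <= 0) abort("`depth` must be positive.")
  if (library_size <= 0 || genome_length <= 0 || n_genes <= 0) {
    abort("Sizes must be positive.")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

# stage-specific sub-seed, kept below 2^31
.stage_seed <- function(config, stage) {
  (as.integer(config$seed) + 7919L * stage) %% .Machine$integer.max
}

#' Simulate a genome with operon structure and ground-truth labels
#'
#' Draws an i.i.d. uniform ACGT circular sequence, packs non-overlapping genes
#' into transcription units (shared strand, geometric sizes), and assigns
#' essential / near-essential / sensitive / host-factor / capsid labels and
#' per-gene fitness effects.
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (a `crispri_genome`), `genes` (gene table with
#'   `tu_id`, `tu_rank`), `tus` ([tu_table()] output) and `truth` (per-gene
#'   tibble: `gene`, `essential`, `near_essential`, `sensitive`,
#'   `host_factor`, `capsid_gene`, `fitness_effect` in log2 per generation at
#'   full silencing).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config, 1L))
  seq <- paste(
    sample(c("A", "C", "G", "T"), config$genome_length, replace = TRUE),
    collapse = ""
  )
  g <- genome(seq, id = sprintf("sim_genome_seed%d", config$seed), circular = TRUE)

  n <- config$n_genes
  lens <- pmax(300L, as.integer(round(rnorm(n, config$gene_length_mean, config$gene_length_sd))))
  # TU sizes: 1 + geometric with mean tu_mean_size
  p <- 1 / max(config$tu_mean_size, 1)
  sizes <- integer(0)
  while (sum(sizes) < n) sizes <- c(sizes, 1L + rgeom(1L, p))
  sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - n)
  sizes <- sizes[sizes > 0L]

  intra_gap <- 20L
  inter_gap <- 150L
  pos <- 200L
  rows <- vector("list", length(sizes))
  gi <- 0L
  for (t in seq_along(sizes)) {
    k <- sizes[t]
    strand <- sample(c("+", "-"), 1L)
    tu_id <- sprintf("TU%03d", t)
    glens <- lens[gi + seq_len(k)]
    starts <- pos + cumsum(c(0L, glens[-k] + intra_gap))
    ends <- starts + glens - 1L
    # transcription order: left->right on +, right->left on -
    rank <- if (strand == "+") seq_len(k) else rev(seq_len(k))
    rows[[t]] <- tibble(
      gene = sprintf("gene%03d", gi + seq_len(k)),
      left = starts, right = ends, strand = strand,
      tu_id = tu_id, tu_rank = rank
    )
    gi <- gi + k
    pos <- max(ends) + inter_gap
  }
  genes <- bind_rows(rows)
  if (max(genes$right) > config$genome_length - 50L) {
    abort("Genes do not fit in genome_length; increase it or reduce n_genes.")
  }

  lab <- sample(
    c("essential", "near_essential", "other"), n,
    replace = TRUE,
    prob = c(
      config$fraction_essential, config$fraction_near_essential,
      1 - config$fraction_essential - config$fraction_near_essential
    )
  )
  essential <- lab == "essential"
  near <- lab == "near_essential"
  sensitive <- essential & runif(n) < config$fraction_sensitive
  pool <- which(!essential & !near)
  if (length(pool) < config$n_host_factors + config$n_capsid_genes) {
    abort("Not enough non-essential genes for host-factor and capsid sets.")
  }
  chosen <- sample(pool, config$n_host_factors + config$n_capsid_genes)
  host_factor <- seq_len(n) %in% chosen[seq_len(config$n_host_factors)]
  capsid <- seq_len(n) %in% chosen[config$n_host_factors + seq_len(config$n_capsid_genes)]

  effect <- numeric(n)
  effect[essential] <- pmin(
    0, rnorm(sum(essential), config$coding_effect_mean, config$coding_effect_sd)
  )
  effect[near] <- pmin(
    0, rnorm(sum(near), config$near_effect_mean, config$near_effect_sd)
  )
  truth <- tibble(
    gene = genes$gene, essential = essential, near_essential = near,
    sensitive = sensitive, host_factor = host_factor, capsid_gene = capsid,
    fitness_effect = effect
  )
  genes$essential <- essential
  genes <- as_gene_table(genes)
  list(genome = g, genes = genes, tus = tu_table(genes), truth = truth)
}

#' Simulate a guide library
#'
#' Uniform sample without replacement from all protospacer sites of the
#' genome, annotated against the gene table, with the non-targeting control
#' guide appended.
#'
#' @param g A `crispri_genome`.
#' @param genes Gene table.
#' @param config A [sim_config()].
#' @return A guide library tibble (see [build_guide_library()]).
#' @export
simulate_library <- function(g, genes, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config, 2L))
  sites <- find_protospacers(g)
  if (config$library_size > nrow(sites)) {
    abort(sprintf(
      "library_size (%d) exceeds available protospacer sites (%d).",
      config$library_size, nrow(sites)
    ))
  }
  picked <- sites[sort(sample.int(nrow(sites), config$library_size)), ]
  build_guide_library(picked, g, genes = genes, add_control = TRUE)
}

#' True per-generation fitness effect of each guide
#'
#' Combines the planted gene effects with the guide's strand relationship,
#' polar propagation down the transcription unit, per-guide repression
#' efficiency and the bad-seed penalty. For each silenced gene the effect is
#' scaled by the repression level: full for coding-strand binding, scaled by
#' `template_effect_scale` for template-strand binding unless the gene is
#' sensitive (sensitive genes pay the full cost even under weak repression).
#' Intergenic guides without a bad seed have zero effect; the control guide
#' always has zero effect.
#'
#' @param library Annotated guide library.
#' @param genes Gene table with `tu_id`, `tu_rank`.
#' @param truth Per-gene truth tibble from [simulate_genome()].
#' @param config A [sim_config()].
#' @return A tibble `guide_id`, `w` (log2 fitness effect per generation),
#'   `repression`, `protects` (silences a host factor at full strength),
#'   `blocks_capsid` (silences a capsid gene at full strength).
#' @export
true_guide_fitness <- function(library, genes, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config, 3L))
  lib <- as_tibble(library)
  n <- nrow(lib)
  repression <- rbeta(n, config$repression_alpha, config$repression_beta)

  gene_info <- genes |>
    select("gene", "tu_id", "tu_rank") |>
    left_join(truth, by = "gene") |>
    select("gene", "tu_id", "tu_rank", "fitness_effect", "sensitive",
      "host_factor", "capsid_gene")

  # per focal gene, summarise its silenced set (itself plus all downstream TU
  # genes when polar): effect sums under full and template-scaled repression,
  # and whether the set contains a host factor / capsid gene
  silenced_summary <- function(df) {
    sum_full <- numeric(nrow(df))
    sum_tmpl <- numeric(nrow(df))
    any_hf <- logical(nrow(df))
    any_cap <- logical(nrow(df))
    for (i in seq_len(nrow(df))) {
      s <- if (config$polar) which(df$tu_rank >= df$tu_rank[i]) else i
      sum_full[i] <- sum(df$fitness_effect[s])
      sum_tmpl[i] <- sum(df$fitness_effect[s] *
        ifelse(df$sensitive[s], 1, config$template_effect_scale))
      any_hf[i] <- any(df$host_factor[s])
      any_cap[i] <- any(df$capsid_gene[s])
    }
    tibble(
      gene = df$gene, sum_full = sum_full, sum_tmpl = sum_tmpl,
      any_hf = any_hf, any_cap = any_cap
    )
  }
  per_gene <- gene_info |>
    mutate(tu_id = if_else(is.na(.data$tu_id), paste0("TU_", .data$gene), .data$tu_id)) |>
    group_by(.data$tu_id) |>
    group_map(~ silenced_summary(.x)) |>
    bind_rows()

  idx <- match(lib$target_gene, per_gene$gene)
  coding <- !is.na(lib$targets_coding) & lib$targets_coding
  targeted <- !is.na(idx) & !lib$is_control
  w <- numeric(n)
  w[targeted] <- repression[targeted] * ifelse(
    coding[targeted],
    per_gene$sum_full[idx[targeted]],
    per_gene$sum_tmpl[idx[targeted]]
  )
  protects <- targeted & coding & per_gene$any_hf[replace(idx, is.na(idx), 1L)]
  blocks_capsid <- targeted & coding & per_gene$any_cap[replace(idx, is.na(idx), 1L)]
  bad <- has_bad_seed(lib$spacer) & !lib$is_control
  w <- w + bad * config$bad_seed_penalty
  w[lib$is_control] <- 0
  tibble(
    guide_id = lib$guide_id, w = w, repression = repression,
    protects = protects, blocks_capsid = blocks_capsid
  )
}

# Count sampling: multinomial at depth, then negative-binomial overdispersion.
.draw_counts <- function(abund, config, sample_names) {
  p <- abund / sum(abund)
  out <- vapply(sample_names, function(s) {
    m <- as.numeric(rmultinom(1L, size = config$depth, prob = p))
    if (config$dispersion > 0) {
      k <- rnbinom(length(m), mu = m, size = 1 / config$dispersion)
      k[m == 0] <- 0
      k
    } else {
      m
    }
  }, numeric(length(abund)))
  matrix(out, nrow = length(abund), dimnames = list(NULL, sample_names))
}

.counts_tbl <- function(lib, mat) {
  bind_cols(tibble(guide_id = lib$guide_id), as_tibble(mat))
}

.paired_design <- function(prefix, n_replicates) {
  screen_design(tibble(
    sample_id = c(
      sprintf("%s_before_%d", prefix, seq_len(n_replicates)),
      sprintf("%s_after_%d", prefix, seq_len(n_replicates))
    ),
    condition = rep(c("before", "after"), each = n_replicates),
    replicate = rep(seq_len(n_replicates), 2L)
  ))
}

#' Simulate the paired growth screen
#'
#' Initial guide abundances are log-normal; after `generations` of growth each
#' abundance is multiplied by `2^(w * generations)`. Counts are multinomial
#' draws at `depth` per sample followed by negative-binomial overdispersion;
#' replicates are independent draws.
#'
#' @param library Guide library tibble.
#' @param guide_truth Output of [true_guide_fitness()].
#' @param config A [sim_config()].
#' @return A list `counts` (tibble), `design` ([screen_design()]),
#'   `abundance` (tibble of true before/after relative abundances).
#' @export
simulate_growth_screen <- function(library, guide_truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config, 4L))
  n <- nrow(library)
  a <- rlnorm(n, meanlog = 0, sdlog = config$abundance_sdlog)
  after <- a * 2^(guide_truth$w * config$generations)
  design <- .paired_design("growth", config$n_replicates)
  mat <- cbind(
    .draw_counts(a, config, design$pairs$before),
    .draw_counts(after, config, design$pairs$after)
  )
  list(
    counts = .counts_tbl(library, mat), design = design,
    abundance = tibble(guide_id = library$guide_id, before = a, after = after)
  )
}

#' Simulate a phage infection screen
#'
#' Cells grow for `pregrowth_generations` with dCas9 induced (growth effects
#' apply), then are infected: a guide's lineage survives at
#' `protection_effect` when it silences a host factor at full strength and at
#' `survival_floor` otherwise (the control guide does not protect).
#'
#' @inheritParams simulate_growth_screen
#' @return As [simulate_growth_screen()].
#' @export
simulate_phage_screen <- function(library, guide_truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config, 5L))
  n <- nrow(library)
  a <- rlnorm(n, meanlog = 0, sdlog = config$abundance_sdlog)
  before <- a * 2^(guide_truth$w * config$pregrowth_generations)
  s <- ifelse(guide_truth$protects, config$protection_effect, config$survival_floor)
  after <- before * s
  design <- .paired_design("phage", config$n_replicates)
  mat <- cbind(
    .draw_counts(before, config, design$pairs$before),
    .draw_counts(after, config, design$pairs$after)
  )
  list(
    counts = .counts_tbl(library, mat), design = design,
    abundance = tibble(guide_id = library$guide_id, before = before, after = after)
  )
}

#' Simulate the cosmid transduction screen
#'
#' Packaged-cosmid output is proportional to the pre-infection abundance
#' (which already reflects growth effects over `pregrowth_generations`), times
#' `2^packaging_penalty` when the guide silences a capsid-competence gene, and
#' proportional to the fraction of cells actually lysed (so lysis-protecting
#' guides also produce few packaged cosmids). As in the experiment, the
#' "before" samples are drawn from the initial pool (before dCas9-induced
#' growth), so transduction log2 fold-changes carry the guides' growth effects
#' on top of the packaging terms.
#'
#' @inheritParams simulate_growth_screen
#' @return As [simulate_growth_screen()].
#' @export
simulate_transduction <- function(library, guide_truth, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(.stage_seed(config, 6L))
  n <- nrow(library)
  a <- rlnorm(n, meanlog = 0, sdlog = config$abundance_sdlog)
  before <- a * 2^(guide_truth$w * config$pregrowth_generations)
  survival <- ifelse(guide_truth$protects, config$protection_effect, config$survival_floor)
  packaged <- before * (1 - survival) *
    2^(config$packaging_penalty * guide_truth$blocks_capsid)
  design <- .paired_design("transduction", config$n_replicates)
  mat <- cbind(
    .draw_counts(a, config, design$pairs$before),
    .draw_counts(packaged, config, design$pairs$after)
  )
  list(
    counts = .counts_tbl(library, mat), design = design,
    abundance = tibble(guide_id = library$guide_id, before = a, after = packaged)
  )
}

#' Simulate a complete screen experiment
#'
#' Runs [simulate_genome()], [simulate_library()], [true_guide_fitness()] and
#' the three count simulators.
#'
#' @param config A [sim_config()].
#' @param screens Which count simulations to run; subset of
#'   `c("growth", "phage", "transduction")`.
#' @return A list `config`, `genome`, `genes`, `tus`, `truth`, `library`,
#'   `guide_truth`, plus one element per simulated screen.
#' @export
simulate_experiment <- function(config,
                                screens = c("growth", "phage", "transduction")) {
  gen <- simulate_genome(config)
  lib <- simulate_library(gen$genome, gen$genes, config)
  gt <- true_guide_fitness(lib, gen$genes, gen$truth, config)
  out <- c(gen, list(config = config, library = lib, guide_truth = gt))
  if ("growth" %in% screens) out$growth <- simulate_growth_screen(lib, gt, config)
  if ("phage" %in% screens) out$phage <- simulate_phage_screen(lib, gt, config)
  if ("transduction" %in% screens) {
    out$transduction <- simulate_transduction(lib, gt, config)
  }
  out
}
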
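test_that("the simulator is deterministic under a seed", {
  cfg <- small_sim(501)
  e1 <- simulate_experiment(cfg)
  e2 <- simulate_experiment(cfg)
  expect_identical(e1$genome$seq, e2$genome$seq)
  expect_identical(e1$library, e2$library)
  expect_identical(e1$guide_truth, e2$guide_truth)
  expect_identical(e1$growth$counts, e2$growth$counts)
  expect_identical(e1$phage$counts, e2$phage$counts)
  expect_identical(e1$transduction$counts, e2$transduction$counts)
  # and byte-identical on disk
  f1 <- tempfile()
  f2 <- tempfile()
  readr::write_tsv(e1$growth$counts, f1)
  readr::write_tsv(e2$growth$counts, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted labels respect the configured fractions", {
  cfg <- small_sim(502, fraction_essential = 0)
  gen <- simulate_genome(cfg)
  expect_equal(sum(gen$truth$essential), 0L)
  expect_equal(sum(gen$truth$sensitive), 0L)

  cfg2 <- small_sim(503)
  gen2 <- simulate_genome(cfg2)
  expect_equal(nrow(gen2$truth), cfg2$n_genes)
  expect_equal(sum(gen2$truth$host_factor), cfg2$n_host_factors)
  expect_equal(sum(gen2$truth$capsid_gene), cfg2$n_capsid_genes)
  # host factors and capsid genes are disjoint and non-essential
  expect_equal(sum(gen2$truth$host_factor & gen2$truth$capsid_gene), 0L)
  expect_true(all(!gen2$truth$essential[gen2$truth$host_factor]))
  # essential genes carry negative fitness effects, others zero
  expect_true(all(gen2$truth$fitness_effect[gen2$truth$essential] < 0))
  ordinary <- !gen2$truth$essential & !gen2$truth$near_essential
  expect_true(all(gen2$truth$fitness_effect[ordinary] == 0))
  # TU structure: ranks unique, strands shared (validated by as_gene_table)
  expect_s3_class(as_gene_table(gen2$genes), "tbl_df")
})

test_that("the sampled library revalidates against the genome", {
  cfg <- small_sim(504)
  gen <- simulate_genome(cfg)
  lib <- simulate_library(gen$genome, gen$genes, cfg)
  expect_equal(sum(!lib$is_control), cfg$library_size)
  # strand balance reflects the site pool (itself near 50/50)
  sites <- find_protospacers(gen$genome)
  pool_plus <- mean(sites$strand == "+")
  expect_gt(pool_plus, 0.45)
  expect_lt(pool_plus, 0.55)
  tab <- table(lib$strand[!lib$is_control])
  bt <- binom.test(tab[["+"]], sum(tab), p = pool_plus)
  expect_gt(bt$p.value, 0.01)
  # every sampled guide re-validates: spacer and NGG PAM at its coordinates
  s2 <- paste0(gen$genome$seq, gen$genome$seq) # circular read-through
  set.seed(1)
  for (i in sample(which(!lib$is_control), 40)) {
    fwd <- substring(s2, lib$start[i], lib$start[i] + 19)
    if (lib$strand[i] == "+") {
      expect_equal(fwd, lib$spacer[i])
      pam <- substring(s2, lib$start[i] + 20, lib$start[i] + 22)
      expect_equal(substring(pam, 2, 3), "GG")
    } else {
      expect_equal(rc_chr(fwd), lib$spacer[i])
      from <- lib$start[i] - 3
      if (from < 1) from <- from + gen$genome$length
      pam <- rc_chr(substring(s2, from, from + 2))
      expect_equal(substring(pam, 2, 3), "GG")
    }
  }
  # asking for more guides than sites fails
  cfg_big <- small_sim(504, library_size = 10 * nrow(find_protospacers(gen$genome)))
  expect_error(simulate_library(gen$genome, gen$genes, cfg_big), "exceeds")
})

test_that("true guide fitness composes strand, polarity and sensitivity", {
  genes <- as_gene_table(tibble::tibble(
    gene = c("ess1", "non1", "ess2", "sens1"),
    left = c(101L, 501L, 701L, 1101L),
    right = c(400L, 700L, 1000L, 1400L),
    strand = c("+", "+", "+", "+"),
    tu_id = c("T1", "T2", "T2", "T3"),
    tu_rank = c(1L, 1L, 2L, 1L)
  ))
  truth <- tibble::tibble(
    gene = genes$gene,
    essential = c(TRUE, FALSE, TRUE, TRUE),
    near_essential = FALSE,
    sensitive = c(FALSE, FALSE, FALSE, TRUE),
    host_factor = FALSE, capsid_gene = FALSE,
    fitness_effect = c(-0.4, 0, -0.5, -0.3)
  )
  cfg <- sim_config(
    seed = 505, polar = TRUE, template_effect_scale = 0.1,
    repression_alpha = 1e6, repression_beta = 1e-6 # repression ~ 1 exactly
  )
  lib <- tibble::tibble(
    guide_id = paste0("q", 1:6),
    spacer = strrep("AC", 10), # no bad seed ("CACAC")
    start = c(150L, 150L, 550L, 550L, 1150L, 1150L),
    strand = c("-", "+", "-", "+", "-", "+"),
    is_control = FALSE
  )
  lib <- annotate_guides(lib, genes)
  ft <- true_guide_fitness(lib, genes, truth, cfg)
  w <- setNames(ft$w, ft$guide_id)
  tol <- 1e-3
  # coding guide on monocistronic essential: its own cost
  expect_equal(unname(w["q1"]), -0.4, tolerance = tol)
  # template guide on non-sensitive essential: scaled by 0.1
  expect_equal(unname(w["q2"]), -0.04, tolerance = tol)
  # coding guide on non-essential with essential downstream: polar cost
  expect_equal(unname(w["q3"]), -0.5, tolerance = tol)
  # template guide upstream: polar cost also scaled
  expect_equal(unname(w["q4"]), -0.05, tolerance = tol)
  # template guide on a sensitive gene: full cost despite weak repression
  expect_equal(unname(w["q6"]), -0.3, tolerance = tol)
  expect_equal(unname(w["q5"]), -0.3, tolerance = tol)

  # polar off: upstream guide has no cost
  cfg_np <- sim_config(
    seed = 505, polar = FALSE,
    repression_alpha = 1e6, repression_beta = 1e-6
  )
  ft_np <- true_guide_fitness(lib, genes, truth, cfg_np)
  expect_equal(ft_np$w[ft_np$guide_id == "q3"], 0, tolerance = tol)

  # bad-seed guides pay the planted penalty
  lib_bs <- lib
  lib_bs$spacer <- paste0(strrep("A", 15), "AGGAA")
  ft_bs <- true_guide_fitness(lib_bs, genes, truth, cfg)
  expect_equal(
    ft_bs$w[ft_bs$guide_id == "q3"] - ft$w[ft$guide_id == "q3"],
    cfg$bad_seed_penalty,
    tolerance = tol
  )
})

test_that("growth screen conserves depth before overdispersion and recovers null", {
  cfg <- small_sim(506, dispersion = 0)
  gen <- simulate_genome(cfg)
  lib <- simulate_library(gen$genome, gen$genes, cfg)
  gt <- true_guide_fitness(lib, gen$genes, gen$truth, cfg)
  growth <- simulate_growth_screen(lib, gt, cfg)
  m <- as.matrix(growth$counts[, -1])
  expect_true(all(colSums(m) == cfg$depth))

  # all-zero effects at high depth without overdispersion: log2fc ~ 0
  cfg0 <- small_sim(507,
    fraction_essential = 0, fraction_near_essential = 0,
    bad_seed_penalty = 0, depth = 1e7, dispersion = 0
  )
  exp0 <- simulate_experiment(cfg0, screens = "growth")
  st0 <- guide_log2fc(
    normalize_by_control(exp0$growth$counts, exp0$growth$design),
    exp0$growth$design
  )
  expect_lt(mean(abs(st0$log2fc)), 0.05)
})

test_that("phage screen enriches protecting guides by the planted margin", {
  cfg <- small_sim(508)
  exp <- simulate_experiment(cfg, screens = "phage")
  st <- guide_log2fc(
    normalize_by_control(exp$phage$counts, exp$phage$design),
    exp$phage$design
  )
  merged <- dplyr::inner_join(st, exp$guide_truth, by = "guide_id")
  margin <- log2(cfg$protection_effect / cfg$survival_floor)
  prot <- merged$log2fc[merged$protects]
  unprot <- merged$log2fc[!merged$protects & merged$guide_id != "control"]
  expect_gt(length(prot), 10)
  expect_gt(mean(prot) - mean(unprot), 0.8 * margin)

  # no host factors: flat screen (no differential enrichment; the common
  # offset from single-control normalization is irrelevant to flatness)
  cfg0 <- small_sim(509,
    n_host_factors = 0, fraction_essential = 0,
    fraction_near_essential = 0, bad_seed_penalty = 0
  )
  exp0 <- simulate_experiment(cfg0, screens = "phage")
  st0 <- guide_stats(exp0$phage$counts, exp0$phage$design)
  expect_lt(sd(st0$log2fc), 0.5)
  expect_lt(mean(st0$padj < 0.05), 0.01)
})

test_that("transduction composes growth, lysis protection and packaging", {
  cfg <- small_sim(510, n_host_factors = 0, n_capsid_genes = 0)
  exp <- simulate_experiment(cfg, screens = c("growth", "transduction"))
  gst <- guide_stats(exp$growth$counts, exp$growth$design)
  tst <- guide_stats(exp$transduction$counts, exp$transduction$design)
  m <- dplyr::inner_join(
    gst |> dplyr::select(guide_id, x = log2fc),
    tst |> dplyr::select(guide_id, y = log2fc),
    by = "guide_id"
  )
  fit <- global_fitness_regression(m$y, m$x)
  expect_gt(fit$slope, 0.8)
  expect_lt(fit$slope, 1.2)

  # capsid guides are depleted ~ packaging_penalty beyond the growth trend
  cfg2 <- small_sim(511)
  exp2 <- simulate_experiment(cfg2, screens = c("growth", "transduction"))
  gst2 <- guide_stats(exp2$growth$counts, exp2$growth$design)
  tst2 <- guide_stats(exp2$transduction$counts, exp2$transduction$design)
  m2 <- dplyr::inner_join(
    gst2 |> dplyr::select(guide_id, x = log2fc),
    tst2 |> dplyr::select(guide_id, y = log2fc),
    by = "guide_id"
  ) |>
    dplyr::inner_join(exp2$guide_truth, by = "guide_id")
  resid <- m2$y - m2$x
  gap <- mean(resid[m2$blocks_capsid & !m2$protects]) -
    mean(resid[!m2$blocks_capsid & !m2$protects & m2$guide_id != "control"])
  expect_lt(abs(gap - cfg2$packaging_penalty), 0.6)
})

test_that("configuration validation rejects impossible setups", {
  expect_error(sim_config(), "mandatory")
  expect_error(sim_config(seed = 1, depth = 0), "positive")
  expect_error(sim_config(seed = 1, fraction_essential = 1.4), "0, 1")
  expect_error(
    simulate_genome(sim_config(seed = 1, genome_length = 5000L, n_genes = 100L)),
    "fit"
  )
})
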
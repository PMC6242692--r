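test_that("bad-seed flag keys on the 5 PAM-proximal bases", {
  expect_true(has_bad_seed("ACGTACGTACGTACGAGGAA"))
  expect_false(has_bad_seed("ACGTACGTACGTACGAAAAA"))
  # all 1024 possible seeds: exactly the 10 configured ones flag
  bases <- c("A", "C", "G", "T")
  all5 <- apply(expand.grid(bases, bases, bases, bases, bases), 1, paste, collapse = "")
  spacers <- paste0(strrep("A", 15), all5)
  expect_equal(sum(has_bad_seed(spacers)), 10L)
})

test_that("a 9-nt suffix match in a promoter window flags the guide", {
  suffix9 <- "CGTACGTAC"
  spacer <- paste0("AAATTTAATTA", suffix9)
  backbone <- strrep("AT", 400)
  # guide's own site at 101 (planted spacer + AGG), off-target 9-mer+TGG at 451,
  # gene starts at 521 on + strand -> off-target midpoint 455 is within
  # [421, 540] = promoter window
  s <- paste0(
    substr(backbone, 1, 100), spacer, "AGG",
    substr(backbone, 1, 327), suffix9, "TGG",
    substr(backbone, 1, 57), strrep("ATGC", 60)
  )
  g <- genome(s, circular = FALSE)
  genes <- as_gene_table(tibble::tibble(
    gene = "gX", left = 521L, right = 700L, strand = "+"
  ))
  guides <- tibble::tibble(
    guide_id = "g1", spacer = spacer, start = 101L, strand = "+", is_control = FALSE
  )
  fl <- offtarget_flags(guides, g, genes)
  expect_true(fl$offtarget_promoter)

  # same guide, gene far away: no flag (own site is excluded)
  genes_far <- as_gene_table(tibble::tibble(
    gene = "gX", left = 900L, right = 1000L, strand = "+"
  ))
  fl2 <- offtarget_flags(guides, g, genes_far)
  expect_false(fl2$offtarget_promoter)
})

test_that("a genome-unique 11-nt suffix gives no off-target flags", {
  s <- random_genome_seq(3000, 101)
  g <- genome(s, circular = TRUE)
  sites <- find_protospacers(g)
  lib <- build_guide_library(sites[1:30, ], g, add_control = FALSE)
  genes <- as_gene_table(tibble::tibble(
    gene = "gX", left = 100L, right = 2900L, strand = "+"
  ))
  # pick guides whose 11-mer suffix occurs exactly once genome-wide
  unique11 <- vapply(lib$spacer, function(sp) {
    nrow(oracle_suffix_sites(sp, 11, s, TRUE)) == 1
  }, logical(1))
  lib1 <- lib[unique11, ]
  fl <- offtarget_flags(lib1, g, genes)
  expect_true(all(!fl$offtarget_coding))
})

test_that("off-target flags match a brute-force oracle on random guides", {
  s <- random_genome_seq(6000, 110)
  g <- genome(s, circular = TRUE)
  genes <- as_gene_table(tibble::tibble(
    gene = c("g1", "g2", "g3"),
    left = c(501L, 2001L, 4001L), right = c(1500L, 3000L, 5000L),
    strand = c("+", "-", "+")
  ))
  sites <- find_protospacers(g)
  set.seed(111)
  lib <- build_guide_library(sites[sample(nrow(sites), 50), ], g,
    genes = genes, add_control = FALSE
  )
  cfg <- qc_config()
  fl <- offtarget_flags(lib, g, genes, cfg)

  # oracle: promoter windows on each gene's strand
  pw <- data.frame(
    left = ifelse(genes$strand == "+", genes$left - 100, genes$right - 19),
    right = ifelse(genes$strand == "+", genes$left + 19, genes$right + 100)
  )
  for (i in seq_len(nrow(lib))) {
    hits9 <- oracle_suffix_sites(lib$spacer[i], 9, s, TRUE)
    # exclude own site: the 9-mer of the on-target site starts at
    # start+11 (+) or start (-)
    own9 <- if (lib$strand[i] == "+") lib$start[i] + 11L else lib$start[i]
    hits9 <- hits9[!(hits9$kmer_start == own9 & hits9$strand == lib$strand[i]), ]
    mids9 <- hits9$kmer_start + 4L
    prom <- any(vapply(mids9, function(m) any(m >= pw$left & m <= pw$right), logical(1)))
    expect_identical(fl$offtarget_promoter[i], prom, info = paste("guide", i))

    hits11 <- oracle_suffix_sites(lib$spacer[i], 11, s, TRUE)
    own11 <- if (lib$strand[i] == "+") lib$start[i] + 9L else lib$start[i]
    hits11 <- hits11[!(hits11$kmer_start == own11 & hits11$strand == lib$strand[i]), ]
    mids11 <- hits11$kmer_start + 5L
    cod <- FALSE
    for (j in seq_len(nrow(hits11))) {
      inside <- genes$left <= mids11[j] & genes$right >= mids11[j]
      cod <- cod || any(inside & genes$strand != hits11$strand[j])
    }
    expect_identical(fl$offtarget_coding[i], cod, info = paste("guide", i))
  }
})

test_that("count filters apply the read floors", {
  counts <- tibble::tibble(
    guide_id = c("a", "b", "control"),
    s1 = c(5, 20, 50), s2 = c(5, 20, 50), s3 = c(5, 0, 50)
  )
  fl <- count_filters(counts, mode = "growth")
  expect_equal(fl$low_reads, c(TRUE, FALSE, FALSE)) # 15 < 20 <= 40
  expect_true(all(!fl$low_base_mean))

  counts2 <- tibble::tibble(
    guide_id = c("a", "b", "control"),
    s1 = c(400, 5000, 500), s2 = c(400, 5000, 500)
  )
  fl2 <- count_filters(counts2, mode = "phage")
  # base means on the unit-geometric-mean scale: 400/1 = 400 and 5000
  expect_equal(fl2$low_base_mean, c(FALSE, FALSE, FALSE))
  counts2$s1[1] <- 3
  counts2$s2[1] <- 3
  expect_true(count_filters(counts2, mode = "phage")$low_base_mean[1])

  expect_error(count_filters(tibble::tibble(guide_id = character(0))), "Empty")
})

test_that("count filters equal direct recomputation on a random matrix", {
  set.seed(120)
  counts <- tibble::tibble(guide_id = c(paste0("g", 1:49), "control"))
  for (s in paste0("s", 1:4)) counts[[s]] <- rpois(50, 12)
  counts[counts$guide_id == "control", -1] <- as.list(rep(100, 4))
  fl <- count_filters(counts, mode = "growth")
  m <- as.matrix(counts[, -1])
  expect_equal(fl$low_reads, rowSums(m) < 20)
})

test_that("apply_qc retains clean guides, drops each violation, keeps control", {
  s <- random_genome_seq(5000, 130)
  g <- genome(s, circular = TRUE)
  genes <- as_gene_table(tibble::tibble(
    gene = "gX", left = 1000L, right = 2000L, strand = "+"
  ))
  sites <- find_protospacers(g)
  lib <- build_guide_library(sites[1:40, ], g, genes = genes)
  cfg <- qc_config()
  # make library clean: keep only guides without any flag
  fl0 <- offtarget_flags(lib, g, genes, cfg)
  clean <- lib[!has_bad_seed(lib$spacer) & !fl0$offtarget_promoter &
    !fl0$offtarget_coding & lib$n_perfect_sites <= 1, ]
  res <- apply_qc(clean, g, genes, counts = NULL, config = cfg)
  expect_equal(nrow(res$retained), nrow(clean))
  expect_equal(res$summary$n[res$summary$reason == "retained"], nrow(clean))

  # bad-seed violation: forge seeds
  bad <- clean
  bad$spacer[!bad$is_control] <- paste0(
    substr(bad$spacer[!bad$is_control], 1, 15), "AGGAA"
  )
  res_bad <- apply_qc(bad, g, genes, counts = NULL, config = cfg)
  expect_true(all(res_bad$retained$is_control))
  expect_equal(
    res_bad$summary$n[res_bad$summary$reason == "bad_seed"],
    sum(!bad$is_control)
  )

  # control guide must be present
  expect_error(
    apply_qc(clean[!clean$is_control, ], g, genes, counts = NULL, config = cfg),
    "control"
  )
})

test_that("QC flags are conjunction-independent and report is consistent", {
  s <- random_genome_seq(5000, 140)
  g <- genome(s, circular = TRUE)
  genes <- as_gene_table(tibble::tibble(
    gene = "gX", left = 1000L, right = 2000L, strand = "+"
  ))
  sites <- find_protospacers(g)
  lib <- build_guide_library(sites[1:60, ], g, genes = genes)
  counts <- tibble::tibble(guide_id = lib$guide_id)
  set.seed(141)
  for (sn in c("b1", "a1")) counts[[sn]] <- rpois(nrow(lib), 50)
  res <- apply_qc(lib, g, genes, counts = counts, config = qc_config())
  rep <- res$report
  # retained == no flag set (control exempt)
  flags <- rep[, c(
    "bad_seed", "offtarget_promoter", "offtarget_coding", "multi_target",
    "low_reads", "low_base_mean"
  )]
  manual <- !Reduce(`|`, flags) | lib$is_control
  expect_equal(rep$retained, manual)
  # summary counts match per-guide flags
  for (cn in names(flags)) {
    expect_equal(res$summary$n[res$summary$reason == cn], sum(rep[[cn]]))
  }
})

test_that("simulated default-rate exclusions match the planted construction", {
  cfg <- small_sim(202)
  exp <- simulate_experiment(cfg, screens = "growth")
  res <- apply_qc(exp$library, exp$genome, exp$genes,
    counts = exp$growth$counts, config = qc_config(), mode = "growth"
  )
  n_bad <- sum(has_bad_seed(exp$library$spacer) & !exp$library$is_control)
  # 10/1024 of random spacers carry a bad seed; binomial 3-sigma band
  n <- sum(!exp$library$is_control)
  p0 <- 10 / 1024
  expect_gt(n_bad, n * p0 - 3 * sqrt(n * p0 * (1 - p0)))
  expect_lt(n_bad, n * p0 + 3 * sqrt(n * p0 * (1 - p0)))
  expect_equal(
    res$summary$n[res$summary$reason == "bad_seed"],
    sum(has_bad_seed(exp$library$spacer))
  )
})
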
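test_that("genome constructor validates input", {
  expect_error(genome(sub("A", "N", strrep("ACGT", 100))), "ACGT")
  expect_error(genome("ACGTACGT"), "longer")
  g <- genome(strrep("ACGT", 10), id = "x", circular = FALSE)
  expect_s3_class(g, "crispri_genome")
  expect_equal(g$length, 40L)
})

test_that("protospacer enumeration finds exactly the NGG-adjacent windows", {
  g <- genome("AAAAAAAAAAAAAAAAAAAAAAGGTT", circular = FALSE)
  sites <- find_protospacers(g)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$strand, "+")
  expect_equal(sites$spacer, strrep("A", 20))
  expect_equal(sites$pam, "AGG")

  g0 <- genome(strrep("A", 30), circular = FALSE)
  expect_equal(nrow(find_protospacers(g0)), 0L)
})

test_that("protospacer enumeration matches the brute-force oracle", {
  for (seed in 1:20) {
    n <- sample(c(500, 1000, 2000, 5000, 10000), 1)
    s <- random_genome_seq(n, seed)
    for (circ in c(FALSE, TRUE)) {
      g <- genome(s, circular = circ)
      mine <- as.data.frame(find_protospacers(g)[, c("start", "strand", "spacer")])
      mine$start <- as.integer(mine$start)
      ora <- oracle_protospacers(s, circ)
      ora$start <- as.integer(ora$start)
      expect_equal(mine, ora, info = sprintf("seed %d circular %s", seed, circ))
    }
  }
})

test_that("enumeration is reverse-complement symmetric", {
  s <- random_genome_seq(3000, 99)
  g <- genome(s, circular = FALSE)
  g_rc <- genome(rc_chr(s), circular = FALSE)
  a <- find_protospacers(g)
  b <- find_protospacers(g_rc)
  expect_equal(nrow(a), nrow(b))
  expect_equal(sort(a$spacer), sort(b$spacer))
  # a + site starting at i maps to a - site starting at L - (i + 19) + 1
  L <- nchar(s)
  mapped <- sort(L - (a$start + 19L) + 1L)
  expect_equal(sort(b$start), mapped)
})

test_that("perfect-site counting is exact by construction and by oracle", {
  set.seed(5)
  cassette <- paste0(
    random_genome_seq(30, 51), "GATCGATCGATCACGTACGT", "TGG", random_genome_seq(30, 52)
  )
  one <- genome(paste0(random_genome_seq(40, 53), cassette), circular = FALSE)
  two <- genome(paste0(cassette, cassette), circular = FALSE)
  expect_equal(count_perfect_sites("GATCGATCGATCACGTACGT", one), 1L)
  expect_equal(count_perfect_sites("GATCGATCGATCACGTACGT", two), 2L)

  s <- random_genome_seq(4000, 54)
  g <- genome(s, circular = TRUE)
  sites <- find_protospacers(g)
  set.seed(55)
  pick <- sample(nrow(sites), 25)
  rand_spacers <- replicate(25, paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""))
  for (sp in c(sites$spacer[pick], rand_spacers)) {
    expect_equal(
      count_perfect_sites(sp, g),
      nrow(oracle_suffix_sites(sp, 20, s, TRUE))
    )
  }
})

test_that("PAM-proximal matching agrees with count_perfect_sites at k = 20", {
  s <- random_genome_seq(3000, 60)
  g <- genome(s, circular = TRUE)
  sites <- find_protospacers(g)
  set.seed(61)
  for (sp in sites$spacer[sample(nrow(sites), 15)]) {
    m20 <- match_pam_proximal(sp, 20, g)
    expect_equal(nrow(m20), count_perfect_sites(sp, g))
  }
})

test_that("a planted 9-nt PAM-proximal match is found", {
  suffix9 <- "CGTACGTAC"
  spacer <- paste0("AAATTTCCGGA", suffix9)
  expect_equal(nchar(spacer), 20L)
  # plant suffix + TGG once, embedded in a GG/CC-free backbone
  backbone <- strrep("AT", 200)
  s <- paste0(
    substr(backbone, 1, 100), suffix9, "TGG", substr(backbone, 1, 150)
  )
  g <- genome(s, circular = FALSE)
  hits <- match_pam_proximal(spacer, 9, g)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$kmer_start, 101L)
})

test_that("PAM-proximal matching equals the brute-force suffix scan", {
  s <- random_genome_seq(3000, 70)
  for (circ in c(FALSE, TRUE)) {
    g <- genome(s, circular = circ)
    sites <- find_protospacers(g)
    set.seed(71)
    for (sp in sites$spacer[sample(nrow(sites), 10)]) {
      for (k in c(9, 11)) {
        mine <- as.data.frame(match_pam_proximal(sp, k, g)[, c("strand", "kmer_start")])
        mine <- mine[order(mine$kmer_start, mine$strand), ]
        rownames(mine) <- NULL
        mine$kmer_start <- as.integer(mine$kmer_start)
        ora <- oracle_suffix_sites(sp, k, s, circ)
        ora <- ora[, c("strand", "kmer_start")]
        ora$kmer_start <- as.integer(ora$kmer_start)
        expect_equal(mine, ora)
      }
    }
  }
})

test_that("guide annotation follows the strand convention and midpoint rule", {
  genes <- as_gene_table(toy_genes())
  # protospacer on -, gene on + -> sgRNA hybridizes to + = coding strand
  guides <- tibble::tibble(
    guide_id = c("q1", "q2", "q3"),
    start = c(150L, 150L, 320L), # midpoints 159, 159, 329
    strand = c("-", "+", "+"),
    is_control = FALSE
  )
  ann <- annotate_guides(guides, genes)
  expect_equal(ann$target_gene, c("gA", "gA", NA))
  expect_equal(ann$targets_coding, c(TRUE, FALSE, NA))
})

test_that("annotation equals interval-containment oracle on random guides", {
  genes <- as_gene_table(toy_genes())
  set.seed(80)
  guides <- tibble::tibble(
    guide_id = paste0("g", 1:10),
    start = sample(1:950, 10),
    strand = sample(c("+", "-"), 10, TRUE),
    is_control = FALSE
  )
  ann <- annotate_guides(guides, genes)
  for (i in 1:10) {
    mid <- guides$start[i] + 9L
    expected <- oracle_assign_gene(mid, genes)
    expect_identical(ann$target_gene[i], expected)
    if (!is.na(expected)) {
      gstrand <- genes$strand[genes$gene == expected]
      expect_identical(ann$targets_coding[i], guides$strand[i] != gstrand)
    }
  }
})

test_that("overlapping genes resolve deterministically by left then name", {
  genes <- as_gene_table(tibble::tibble(
    gene = c("zz", "aa"), left = c(100L, 100L), right = c(400L, 400L),
    strand = c("+", "+")
  ))
  ann <- annotate_guides(
    tibble::tibble(guide_id = "g", start = 200L, strand = "+", is_control = FALSE),
    genes
  )
  expect_equal(ann$target_gene, "aa")
})

test_that("library construction tallies perfect sites correctly", {
  s <- random_genome_seq(5000, 90)
  g <- genome(s, circular = TRUE)
  sites <- find_protospacers(g)
  lib <- build_guide_library(sites[1:50, ], g, genes = NULL)
  expect_true(all(lib$n_perfect_sites[!lib$is_control] >= 1L))
  set.seed(91)
  for (i in sample(50, 8)) {
    expect_equal(lib$n_perfect_sites[i], count_perfect_sites(lib$spacer[i], g))
  }
  ctrl <- lib[lib$is_control, ]
  expect_equal(nrow(ctrl), 1L)
  expect_equal(ctrl$spacer, control_spacer())
  expect_true(is.na(ctrl$target_gene))
  expect_equal(ctrl$seed5, substr(control_spacer(), 16, 20))
})

test_that("FASTA and gene table round-trips preserve content", {
  s <- random_genome_seq(500, 95)
  g <- genome(s, id = "chr", circular = FALSE)
  fa <- tempfile(fileext = ".fasta")
  write_genome(g, fa)
  g2 <- read_genome(fa, circular = FALSE)
  expect_equal(g2$seq, g$seq)
  expect_equal(g2$id, "chr")

  tsv <- tempfile(fileext = ".tsv")
  readr::write_tsv(toy_genes(), tsv)
  gt <- read_gene_table(tsv)
  expect_equal(gt$gene, toy_genes()$gene)
  expect_true(all(c("essential", "tu_id", "tu_rank") %in% names(gt)))
})
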
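#' Pipeline configuration
#'
#' Bundles the simulator configuration, QC configuration and analysis
#' thresholds for [run_pipeline()].
#'
#' @param seed Integer seed driving all randomness.
#' @param sim A [sim_config()]; defaults to `sim_config(seed)`.
#' @param qc A [qc_config()].
#' @param essential_threshold Essentiality cutoff on the coding-strand median
#'   log2FC, default -2.
#' @param padj_threshold Guide-level significance threshold for the volcano
#'   plot, default 1e-3.
#' @param resistance_fraction Fraction-of-maximum rule for resistance hits,
#'   default 0.2.
#' @param fdr_threshold FDR cutoff for transduction hits, default 0.05.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed,
                            sim = sim_config(seed),
                            qc = qc_config(),
                            essential_threshold = -2,
                            padj_threshold = 1e-3,
                            resistance_fraction = 0.2,
                            fdr_threshold = 0.05) {
  stopifnot(inherits(sim, "sim_config"), inherits(qc, "qc_config"))
  thr <- c(essential_threshold, padj_threshold, resistance_fraction, fdr_threshold)
  if (any(!is.finite(thr))) abort("Thresholds must be finite.")
  structure(
    list(
      seed = seed, sim = sim, qc = qc,
      essential_threshold = essential_threshold,
      padj_threshold = padj_threshold,
      resistance_fraction = resistance_fraction,
      fdr_threshold = fdr_threshold
    ),
    class = "pipeline_config"
  )
}

.config_hash <- function(config) {
  flat <- unlist(config[c("seed", "essential_threshold", "padj_threshold",
    "resistance_fraction", "fdr_threshold")])
  sprintf("%08x", sum(utf8ToInt(paste(names(flat), flat, collapse = ";"))) %% 0xFFFFFFF)
}

.write_stamped_csv <- function(x, path, config) {
  header <- sprintf(
    "# crispriscreen %s | seed=%s | config=%s",
    as.character(utils::packageVersion("crispriscreen")),
    config$seed, .config_hash(config)
  )
  writeLines(header, path)
  suppressWarnings(readr::write_csv(x, path, append = TRUE, col_names = TRUE))
  invisible(path)
}

#' Read a pipeline CSV artifact
#'
#' Skips the provenance header comment written by [run_pipeline()].
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_artifact <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Run the screen analysis pipeline
#'
#' Executes the requested stages in dependency order on a simulated
#' experiment: `simulate` (genome, library, counts), `qc` (guide filters),
#' `fitness` (guide statistics for the growth screen), `score` (gene scores,
#' essentiality calls, ROC against planted truth), `operon` (polar-effect
#' classification), `phage` (resistance scores and hits), `transduction`
#' (per-gene nested linear model) and `report` (markdown summary + figures).
#' Every output CSV starts with a header comment recording the package
#' version, seed and configuration hash; a run log records guide and gene
#' counts at each stage.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if missing).
#' @param stages Character vector of stages; defaults to all, and earlier
#'   stages required by a requested stage are run automatically.
#' @return Invisibly, a list with all in-memory artifacts plus `log` (tibble
#'   of stage messages) and `outdir`.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c(
                           "simulate", "qc", "fitness", "score",
                           "operon", "phage", "transduction", "report"
                         )) {
  stopifnot(inherits(config, "pipeline_config"))
  all_stages <- c(
    "simulate", "qc", "fitness", "score", "operon", "phage",
    "transduction", "report"
  )
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  # run every prerequisite of the latest requested stage
  need <- all_stages[seq_len(max(match(stages, all_stages)))]
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logs <- list()
  note <- function(stage, msg) {
    logs[[length(logs) + 1L]] <<- tibble(stage = stage, message = msg)
    message("[", stage, "] ", msg)
  }

  exp <- simulate_experiment(config$sim)
  write_genome(exp$genome, file.path(outdir, "genome.fasta"))
  readr::write_tsv(exp$genes, file.path(outdir, "genes.tsv"))
  readr::write_tsv(exp$tus, file.path(outdir, "tus.tsv"))
  .write_stamped_csv(exp$library, file.path(outdir, "library.csv"), config)
  .write_stamped_csv(exp$truth, file.path(outdir, "ground_truth.csv"), config)
  readr::write_tsv(exp$growth$counts, file.path(outdir, "counts_growth.tsv"))
  readr::write_tsv(exp$phage$counts, file.path(outdir, "counts_phage.tsv"))
  readr::write_tsv(exp$transduction$counts, file.path(outdir, "counts_transduction.tsv"))
  note("simulate", sprintf(
    "%d genes, %d guides (+control), 3 screens at depth %g",
    nrow(exp$genes), sum(!exp$library$is_control), config$sim$depth
  ))
  res <- list(config = config, experiment = exp, outdir = outdir)
  if (identical(need, "simulate")) {
    res$log <- bind_rows(logs)
    return(invisible(res))
  }

  qc <- apply_qc(
    exp$library, exp$genome, exp$genes,
    counts = exp$growth$counts, config = config$qc, mode = "growth"
  )
  write_qc_report(
    qc, file.path(outdir, "qc_report.csv"), file.path(outdir, "qc_summary.json")
  )
  note("qc", sprintf(
    "%d of %d guides retained", nrow(qc$retained), nrow(exp$library)
  ))
  res$qc <- qc
  if (max(match(need, all_stages)) < 3L) {
    res$log <- bind_rows(logs)
    return(invisible(res))
  }

  retained_counts <- exp$growth$counts |>
    filter(.data$guide_id %in% qc$retained$guide_id)
  stats <- guide_stats(retained_counts, exp$growth$design)
  write_guide_stats(stats, file.path(outdir, "guide_stats_growth.csv"))
  note("fitness", sprintf("guide statistics for %d guides", nrow(stats)))
  res$guide_stats <- stats

  scores <- score_genes(stats, qc$retained) |>
    call_essential(threshold = config$essential_threshold)
  scores <- scores |>
    left_join(exp$truth |> select("gene", "essential"), by = "gene")
  roc <- tryCatch(
    roc_auc(scores, exp$truth |> select("gene", "essential")),
    error = function(e) NULL
  )
  .write_stamped_csv(scores, file.path(outdir, "gene_scores.csv"), config)
  note("score", sprintf(
    "%d candidate essential genes of %d scored%s",
    sum(scores$candidate_essential), nrow(scores),
    if (is.null(roc)) "" else sprintf(" (AUC = %.3f vs planted truth)", roc$auc)
  ))
  res$gene_scores <- scores
  res$roc <- roc

  op <- classify_genome(
    exp$tus,
    scores |> transmute(.data$gene, depleted = .data$candidate_essential)
  )
  .write_stamped_csv(op$calls, file.path(outdir, "operon_calls.csv"), config)
  note("operon", sprintf(
    "%d confident, %d uncertain, %d internal-promoter candidates",
    op$summary$n_confident, op$summary$n_uncertain, op$summary$n_internal_promoter
  ))
  res$operon <- op

  phage_qc <- apply_qc(
    exp$library, exp$genome, exp$genes,
    counts = exp$phage$counts, config = config$qc, mode = "phage"
  )
  phage_lib <- phage_qc$retained |>
    filter(.data$is_control | (!is.na(.data$targets_coding) & .data$targets_coding))
  phage_counts <- exp$phage$counts |> filter(.data$guide_id %in% phage_lib$guide_id)
  phage_stats <- guide_stats(phage_counts, exp$phage$design)
  rscores <- resistance_score(phage_stats, phage_lib)
  hits <- select_resistant(
    rscores,
    fraction = config$resistance_fraction, min_guides = 2L
  )
  .write_stamped_csv(rscores, file.path(outdir, "resistance_scores.csv"), config)
  note("phage", sprintf(
    "%d genes scored, %d resistance hits", nrow(rscores), length(hits)
  ))
  res$phage_stats <- phage_stats
  res$resistance <- rscores
  res$resistance_hits <- hits

  td_counts <- exp$transduction$counts |>
    filter(.data$guide_id %in% phage_lib$guide_id)
  td_stats <- guide_stats(td_counts, exp$transduction$design)
  merged <- td_stats |>
    select("guide_id", td_log2fc = "log2fc") |>
    inner_join(stats |> select("guide_id", growth_log2fc = "log2fc"), by = "guide_id") |>
    inner_join(
      phage_lib |> select("guide_id", "target_gene", "is_control"),
      by = "guide_id"
    ) |>
    filter(!.data$is_control)
  tstats <- host_factor_screen(
    merged$target_gene, merged$td_log2fc, merged$growth_log2fc,
    fdr_threshold = config$fdr_threshold
  )
  gfit <- global_fitness_regression(merged$td_log2fc, merged$growth_log2fc)
  write_transduction_stats(tstats, file.path(outdir, "transduction_stats.csv"))
  note("transduction", sprintf(
    "%d genes tested, %d hits (FDR < %.2g); global slope %.2f",
    nrow(tstats), sum(tstats$hit), config$fdr_threshold, gfit$slope
  ))
  res$transduction_stats <- tstats
  res$global_fit <- gfit

  if ("report" %in% need) {
    res$report <- make_report(res, outdir)
    note("report", "markdown report and figures written")
  }
  res$log <- bind_rows(logs)
  readr::write_tsv(res$log, file.path(outdir, "run_log.tsv"))
  invisible(res)
}

#' Write a markdown report with summary figures
#'
#' Produces `report.md` plus PNG figures: ROC curve, gene rank plot,
#' coding-vs-template scatter, phage volcano (dashed line at the adjusted-p
#' threshold) and transduction estimate-vs-FDR plot. All numbers in the report
#' are taken from the artifact tables.
#'
#' @param artifacts Result list of [run_pipeline()] (needs `gene_scores`,
#'   `roc`, `phage_stats`, `transduction_stats`).
#' @param outdir Directory for `report.md` and `figures/`.
#' @return Path to `report.md`, invisibly.
#' @export
make_report <- function(artifacts, outdir) {
  figdir <- file.path(outdir, "figures")
  dir.create(figdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- artifacts$config
  lines <- c(
    "# CRISPRi screen report",
    "",
    sprintf("Seed: %s; config hash: %s", cfg$seed, .config_hash(cfg)),
    ""
  )
  save_fig <- function(p, name) {
    path <- file.path(figdir, name)
    ggplot2::ggsave(path, p, width = 6, height = 4, dpi = 120)
    path
  }
  if (!is.null(artifacts$roc)) {
    save_fig(plot_roc(artifacts$roc), "roc.png")
    lines <- c(lines, sprintf(
      "- Essentiality AUC vs planted truth: %.3f (%d positives / %d negatives)",
      artifacts$roc$auc, artifacts$roc$n_pos, artifacts$roc$n_neg
    ))
  }
  if (!is.null(artifacts$gene_scores) && nrow(artifacts$gene_scores)) {
    save_fig(
      plot_gene_ranks(artifacts$gene_scores, cfg$essential_threshold),
      "gene_ranks.png"
    )
    save_fig(plot_strand_scatter(artifacts$gene_scores), "strand_scatter.png")
    lines <- c(lines, sprintf(
      "- Candidate essential genes (median coding log2FC < %g): %d of %d scored",
      cfg$essential_threshold,
      sum(artifacts$gene_scores$candidate_essential),
      nrow(artifacts$gene_scores)
    ))
  } else {
    lines <- c(lines, "- Gene score table empty: no rank or scatter plot produced.")
  }
  if (!is.null(artifacts$operon)) {
    s <- artifacts$operon$summary
    lines <- c(lines, sprintf(
      "- Operon-aware calls: %d confidently essential, %d uncertain, %d internal-promoter candidates",
      s$n_confident, s$n_uncertain, s$n_internal_promoter
    ))
  }
  if (!is.null(artifacts$phage_stats) && nrow(artifacts$phage_stats)) {
    save_fig(plot_volcano(artifacts$phage_stats, cfg$padj_threshold), "phage_volcano.png")
    lines <- c(lines, sprintf(
      "- Phage screen: %d resistance hits (score > %g of maximum, >1 guide)",
      length(artifacts$resistance_hits), cfg$resistance_fraction
    ))
  } else {
    lines <- c(lines, "- Phage guide statistics empty: no volcano plot produced.")
  }
  if (!is.null(artifacts$transduction_stats) && nrow(artifacts$transduction_stats)) {
    save_fig(
      plot_transduction(artifacts$transduction_stats, cfg$fdr_threshold),
      "transduction.png"
    )
    lines <- c(lines, sprintf(
      "- Transduction model: %d of %d genes are hits at FDR < %g",
      sum(artifacts$transduction_stats$hit), nrow(artifacts$transduction_stats),
      cfg$fdr_threshold
    ))
  } else {
    lines <- c(lines, "- Transduction table empty: no estimate-FDR plot produced.")
  }
  path <- file.path(outdir, "report.md")
  writeLines(lines, path)
  invisible(path)
}
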
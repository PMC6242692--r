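#' Aggregate guide statistics to gene level
#'
#' For every targeted gene, the median and (unscaled) median absolute
#' deviation of guide log2 fold-changes are computed separately for guides
#' hybridizing to the coding strand and to the template strand. Gene ranking
#' and all essentiality / resistance calls use the coding-strand median:
#' coding-strand binding blocks the elongating RNA polymerase and gives strong
#' repression, template-strand binding only partial repression.
#'
#' @param stats Guide statistics tibble (needs `guide_id`, `log2fc`).
#' @param library Annotated guide library (needs `guide_id`, `target_gene`,
#'   `targets_coding`, `is_control`). QC-failed and multi-target guides are
#'   expected to have been removed already.
#' @return A tibble with one row per targeted gene: `gene`, `n_coding`,
#'   `n_template`, `median_coding`, `mad_coding`, `median_template`,
#'   `mad_template`. Medians are `NA` when no guide of that class targets the
#'   gene.
#' @export
score_genes <- function(stats, library) {
  dat <- as_tibble(library) |>
    filter(!.data$is_control, !is.na(.data$target_gene), !is.na(.data$targets_coding)) |>
    inner_join(as_tibble(stats), by = "guide_id")
  med0 <- function(x) if (length(x)) median(x) else NA_real_
  mad0 <- function(x) if (length(x)) median(abs(x - median(x))) else NA_real_
  dat |>
    group_by(gene = .data$target_gene) |>
    summarise(
      n_coding = sum(.data$targets_coding),
      n_template = sum(!.data$targets_coding),
      median_coding = med0(.data$log2fc[.data$targets_coding]),
      mad_coding = mad0(.data$log2fc[.data$targets_coding]),
      median_template = med0(.data$log2fc[!.data$targets_coding]),
      mad_template = mad0(.data$log2fc[!.data$targets_coding]),
      .groups = "drop"
    ) |>
    arrange(.data$median_coding)
}

#' Call candidate essential genes
#'
#' A gene is a candidate essential when the median log2 fold-change of its
#' coding-strand guides is strictly below `threshold` (default -2): guides
#' silencing genes required for growth are depleted from the library.
#'
#' @param scores Gene score tibble from [score_genes()].
#' @param threshold Strict cutoff on `median_coding`, default -2.
#' @return `scores` with a logical `candidate_essential` column (`FALSE` for
#'   genes without coding-strand guides).
#' @export
call_essential <- function(scores, threshold = -2) {
  scores |>
    mutate(
      candidate_essential = !is.na(.data$median_coding) & .data$median_coding < threshold
    )
}

#' ROC curve and AUC for essentiality prediction
#'
#' Genes are ranked by depletion (`-median_coding`, most depleted first) and
#' compared to a gold-standard label. The AUC is computed by the rank
#' (Mann-Whitney) formula with midrank tie correction; the curve is evaluated
#' at every distinct threshold.
#'
#' @param scores Gene score tibble (needs `gene`, `median_coding`).
#' @param gold A data frame with columns `gene` and `essential` (logical), or a
#'   logical vector aligned with `scores$gene`.
#' @return A list with `auc` (number), `curve` (tibble `fpr`, `tpr`) and `n_pos`,
#'   `n_neg`.
#' @export
roc_auc <- function(scores, gold) {
  if (is.data.frame(gold)) {
    dat <- scores |>
      select("gene", "median_coding") |>
      inner_join(as_tibble(gold) |> select("gene", "essential"), by = "gene")
    labels <- as.logical(dat$essential)
    score <- -dat$median_coding
  } else {
    labels <- as.logical(gold)
    score <- -scores$median_coding
  }
  keep <- !is.na(score) & !is.na(labels)
  score <- score[keep]
  labels <- labels[keep]
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    abort("Need at least one positive and one negative label.")
  }
  r <- rank(score) # midranks handle ties
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)

  ord <- order(score, decreasing = TRUE)
  s_sorted <- score[ord]
  l_sorted <- labels[ord]
  # curve points at each distinct threshold
  idx <- which(!duplicated(s_sorted, fromLast = TRUE))
  tp <- cumsum(l_sorted)[idx]
  fp <- cumsum(!l_sorted)[idx]
  curve <- tibble(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
  list(auc = auc, curve = curve, n_pos = n_pos, n_neg = n_neg)
}

#' Phage-resistance score per gene
#'
#' The resistance score of a gene is the median log2 fold-change of its
#' coding-strand guides in a phage screen: guides that silence a host factor
#' protect the cell from lysis and are enriched, so protective genes score
#' positive.
#'
#' @inheritParams score_genes
#' @return Gene score tibble with `resistance_score` (`= median_coding`)
#'   added, sorted by decreasing score.
#' @export
resistance_score <- function(stats, library) {
  score_genes(stats, library) |>
    mutate(resistance_score = .data$median_coding) |>
    arrange(desc(.data$resistance_score))
}

#' Select resistance hits
#'
#' Genes targeted by at least `min_guides` coding-strand guides whose
#' resistance score exceeds `fraction` of the maximum observed score.
#'
#' @param scores Output of [resistance_score()].
#' @param fraction Fraction of the maximum score, default 0.2.
#' @param min_guides Minimum number of coding-strand guides, default 2.
#' @return Character vector of selected genes (empty, with a warning, when no
#'   score is positive).
#' @export
select_resistant <- function(scores, fraction = 0.2, min_guides = 2L) {
  rs <- scores$resistance_score
  if (all(is.na(rs)) || max(rs, na.rm = TRUE) <= 0) {
    warn("No positive resistance score; returning an empty selection.")
    return(character(0))
  }
  cutoff <- fraction * max(rs, na.rm = TRUE)
  scores |>
    filter(
      .data$n_coding >= min_guides,
      !is.na(.data$resistance_score),
      .data$resistance_score > cutoff
    ) |>
    pull("gene")
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact test (minimum-likelihood method) with the conditional
#' maximum-likelihood odds ratio; computed from the hypergeometric
#' distribution in a numerically safe way so that p-values far below 1e-40
#' are returned exactly rather than underflowing to 0.
#'
#' @param a,b,c,d Cell counts: `a` and `b` are successes/failures in group 1,
#'   `c` and `d` in group 2.
#' @return A list with `odds_ratio` and `p_value`.
#' @export
#'
#' @examples
#' fisher_exact_2x2(348, 1584, 6117, 76699)$p_value
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort("Cell counts must be non-negative integers.")
  }
  tab <- matrix(cells, nrow = 2L, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("Fisher test requires positive margins.")
  }
  ft <- fisher.test(tab)
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Mann-Whitney U test for a guide set
#'
#' Compares the log2 fold-changes of a set of guides (for instance all guides
#' of one operon) against all remaining guides, two-sided, with the normal
#' approximation and tie correction.
#'
#' @param stats Guide statistics tibble (`guide_id`, `log2fc`).
#' @param member_guide_ids Guide ids forming the set; must be a non-empty
#'   proper subset of `stats$guide_id`.
#' @return A list with `U` (statistic for the member set) and `p_value`.
#' @export
geneset_mannwhitney <- function(stats, member_guide_ids) {
  stats <- as_tibble(stats)
  member <- stats$guide_id %in% member_guide_ids
  if (!any(member) || all(member)) {
    abort("Member set must be a non-empty proper subset of the guides.")
  }
  x <- stats$log2fc[member]
  y <- stats$log2fc[!member]
  if (length(unique(c(x, y))) == 1L) {
    return(list(U = length(x) * length(y) / 2, p_value = 1))
  }
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = FALSE, correct = FALSE)
  )
  list(U = unname(wt$statistic), p_value = wt$p.value)
}

#' Compare screens: correlations and hit-set overlaps
#'
#' Pairwise Pearson correlations of gene scores across screens (over the genes
#' scored in every screen) plus the sizes of all intersections of the selected
#' hit sets (Venn-style counts).
#'
#' @param score_tables Named list of gene score tibbles (each with `gene` and
#'   a score column).
#' @param score_col Column to correlate, default `"resistance_score"`.
#' @param hit_sets Optional named list of character vectors of selected genes;
#'   defaults to [select_resistant()] applied to each table.
#' @return A list with `correlation` (matrix), `shared_genes` (number of genes
#'   scored in all screens) and `overlap` (tibble with one row per non-empty
#'   screen combination and the count of genes exclusive to it).
#' @export
compare_screens <- function(score_tables, score_col = "resistance_score",
                            hit_sets = NULL) {
  if (length(score_tables) < 2L) abort("Need at least two score tables.")
  nm <- names(score_tables) %||% paste0("screen", seq_along(score_tables))
  names(score_tables) <- nm
  wide <- purrr::imap(score_tables, function(tb, n) {
    tb |> select("gene", !!n := all_of(score_col))
  }) |>
    purrr::reduce(inner_join, by = "gene") |>
    filter(if_all(-"gene", ~ !is.na(.x)))
  if (nrow(wide) < 3L) abort("Fewer than 3 genes shared across all screens.")
  cm <- cor(as.matrix(wide[nm]), method = "pearson")

  if (is.null(hit_sets)) {
    hit_sets <- purrr::map(score_tables, function(tb) {
      suppressWarnings(select_resistant(tb))
    })
  }
  universe <- unique(unlist(hit_sets))
  membership <- purrr::map(hit_sets, ~ universe %in% .x)
  combo <- do.call(paste, c(purrr::map(membership, ~ ifelse(.x, "1", "0")), sep = ""))
  overlap <- tibble(gene = universe, combo = combo) |>
    count(.data$combo, name = "n") |>
    mutate(screens = purrr::map_chr(.data$combo, function(cb) {
      paste(nm[strsplit(cb, "")[[1]] == "1"], collapse = "&")
    })) |>
    select("screens", "n")
  list(correlation = cm, shared_genes = nrow(wide), overlap = overlap)
}

#' Write a gene score table as CSV
#'
#' Deposited-table-like layout: gene, median_coding, mad_coding,
#' median_template, mad_template, coding, template (+ any extra columns).
#'
#' @param scores Gene score tibble.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_gene_scores <- function(scores, path) {
  out <- scores |>
    rename(coding = "n_coding", template = "n_template")
  readr::write_csv(out, path)
  invisible(path)
}
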
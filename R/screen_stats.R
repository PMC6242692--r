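#' Describe a paired before/after screen design
#'
#' @param samples A data frame with columns `sample_id`, `condition`
#'   (`"before"` or `"after"`) and `replicate` (replicate identifier). Every
#'   replicate must contribute exactly one before and one after sample.
#' @param control_guide_id Identifier of the non-targeting control guide.
#' @return A list of class `screen_design` with elements `samples` (tibble) and
#'   `pairs` (tibble `replicate`, `before`, `after`).
#' @export
#'
#' @examples
#' screen_design(data.frame(
#'   sample_id = c("b1", "a1", "b2", "a2"),
#'   condition = c("before", "after", "before", "after"),
#'   replicate = c(1, 1, 2, 2)
#' ))
screen_design <- function(samples, control_guide_id = CONTROL_GUIDE_ID) {
  samples <- as_tibble(samples)
  req <- c("sample_id", "condition", "replicate")
  if (!all(req %in% names(samples))) {
    abort("`samples` needs columns sample_id, condition, replicate.")
  }
  if (!all(samples$condition %in% c("before", "after"))) {
    abort("condition must be 'before' or 'after'.")
  }
  pairs <- samples |>
    tidyr::pivot_wider(
      id_cols = "replicate", names_from = "condition",
      values_from = "sample_id", values_fn = list
    )
  if (!all(c("before", "after") %in% names(pairs)) ||
    any(lengths(pairs$before) != 1L) || any(lengths(pairs$after) != 1L)) {
    abort("Every replicate must have exactly one before and one after sample.")
  }
  pairs <- pairs |> mutate(before = unlist(.data$before), after = unlist(.data$after))
  if (nrow(pairs) < 1L) abort("Need at least one replicate.")
  structure(
    list(samples = samples, pairs = pairs, control_guide_id = control_guide_id),
    class = "screen_design"
  )
}

.count_matrix <- function(counts) {
  counts <- as_tibble(counts)
  if (!"guide_id" %in% names(counts)) abort("Count table needs a guide_id column.")
  m <- as.matrix(counts[setdiff(names(counts), "guide_id")])
  if (nrow(m) == 0L || ncol(m) == 0L) abort("Empty count matrix.")
  rownames(m) <- counts$guide_id
  storage.mode(m) <- "double"
  m
}

#' Normalize counts by the non-targeting control guide
#'
#' Each sample column is divided by that sample's read count of the control
#' guide, which serves as the size factor. The control row becomes all 1.
#'
#' @param counts Count tibble (`guide_id` + one column per sample).
#' @param design A [screen_design()] (used for the control guide id), or a
#'   guide id string.
#' @return A tibble of the same shape with normalized values, with attribute
#'   `"size_factors"` holding the per-sample control counts.
#' @export
normalize_by_control <- function(counts, design = CONTROL_GUIDE_ID) {
  ctrl_id <- if (inherits(design, "screen_design")) design$control_guide_id else design
  m <- .count_matrix(counts)
  ci <- match(ctrl_id, rownames(m))
  if (is.na(ci)) abort("Control guide not found in count matrix.")
  ctrl <- m[ci, ]
  zero <- names(ctrl)[ctrl == 0]
  if (length(zero)) {
    abort(paste0(
      "Control guide has zero reads in sample(s): ", paste(zero, collapse = ", ")
    ))
  }
  norm <- sweep(m, 2L, ctrl, "/")
  out <- bind_cols(tibble(guide_id = rownames(m)), as_tibble(norm))
  attr(out, "size_factors") <- ctrl
  out
}

#' Per-guide log2 fold-change from a paired design
#'
#' For each replicate the after/before ratio of control-normalized counts is
#' taken, guarded by a pseudocount on the raw-count scale (propagated through
#' normalization, i.e. `pseudocount / control_count` per sample); the log2
#' fold-change is the unweighted mean of the per-replicate log2 ratios.
#' Positive values mean enrichment, negative depletion.
#'
#' @param normalized Output of [normalize_by_control()] (must carry the
#'   `size_factors` attribute).
#' @param design A [screen_design()].
#' @param pseudocount Raw-scale pseudocount, default 0.5.
#' @return A tibble `guide_id`, `log2fc`.
#' @export
guide_log2fc <- function(normalized, design, pseudocount = 0.5) {
  stopifnot(inherits(design, "screen_design"))
  sf <- attr(normalized, "size_factors")
  if (is.null(sf)) abort("`normalized` must come from normalize_by_control().")
  m <- .count_matrix(normalized)
  eps <- pseudocount / sf
  lr <- vapply(seq_len(nrow(design$pairs)), function(r) {
    b <- design$pairs$before[r]
    a <- design$pairs$after[r]
    log2((m[, a] + eps[[a]]) / (m[, b] + eps[[b]]))
  }, numeric(nrow(m)))
  lr <- matrix(lr, nrow = nrow(m))
  tibble(guide_id = rownames(m), log2fc = unname(rowMeans(lr)))
}

#' Base mean of normalized counts
#'
#' Arithmetic mean of the control-normalized counts of each guide across all
#' samples.
#'
#' @param normalized Output of [normalize_by_control()].
#' @return A tibble `guide_id`, `base_mean`.
#' @export
base_mean <- function(normalized) {
  m <- .count_matrix(normalized)
  tibble(guide_id = rownames(m), base_mean = unname(rowMeans(m)))
}

# Median-of-ratios size factors (stable against the single-control noise).
.median_ratio_sf <- function(raw) {
  lg <- log(raw)
  lg[!is.finite(lg)] <- NA
  gm <- rowMeans(lg)
  ok <- is.finite(gm)
  sf <- apply(raw[ok, , drop = FALSE], 2L, function(col) {
    median(exp(log(col[col > 0]) - gm[ok][col > 0]))
  })
  sf[!is.finite(sf) | sf <= 0] <- 1
  sf
}

# Method-of-moments extra-Poisson dispersion of normalized counts.
# Within each condition: var(n_r) ~ m^2 * (phi + mean(1/K_r)); solve for phi.
# Returns per-guide estimates floored at `floor`, shrunk toward the library
# median for stability at small replicate numbers.
.mom_dispersion <- function(raw, norm, groups, floor = 0.01, shrink = 0.25) {
  per_cond <- vapply(unique(groups), function(gr) {
    idx <- which(groups == gr)
    if (length(idx) < 2L) {
      return(rep(NA_real_, nrow(norm)))
    }
    n <- norm[, idx, drop = FALSE]
    k <- raw[, idx, drop = FALSE]
    m <- rowMeans(n)
    v <- apply(n, 1L, var)
    pois <- rowMeans(1 / (k + 0.5))
    est <- v / pmax(m, 1e-12)^2 - pois
    est[m <= 0] <- NA_real_
    est
  }, numeric(nrow(norm)))
  per_cond <- matrix(per_cond, nrow = nrow(norm))
  phi_g <- rowMeans(per_cond, na.rm = TRUE)
  phi_g[!is.finite(phi_g)] <- NA_real_
  # the plain (lightly trimmed) mean is the near-unbiased centre for the
  # right-skewed per-guide moment estimates; the median would undershoot
  phi_ctr <- mean(phi_g, trim = 0.01, na.rm = TRUE)
  if (!is.finite(phi_ctr)) phi_ctr <- floor
  phi <- shrink * ifelse(is.na(phi_g), phi_ctr, phi_g) + (1 - shrink) * phi_ctr
  pmax(phi, floor)
}

#' Negative-binomial Wald test per guide
#'
#' Counts are modelled as negative binomial. The per-guide extra-Poisson
#' dispersion is estimated by the method of moments within each condition on
#' counts normalized with median-of-ratios size factors (floored at
#' `dispersion_floor` and shrunk toward the library median); the variance of
#' the log2 fold-change is propagated from the plug-in negative-binomial
#' variances of each sample, and a two-sided Wald p-value is reported with
#' Benjamini-Hochberg adjustment across guides.
#'
#' Because a single non-targeting guide is the normalization factor, its
#' sampling noise shifts all log2 fold-changes of a replicate together. The
#' Wald statistic is therefore computed on per-replicate median-centered log
#' ratios -- testing whether a guide's fold-change differs from the
#' library-typical fold-change -- while the reported `log2fc` stays on the
#' control-normalized scale.
#'
#' With a single replicate no dispersion can be estimated: all p-values are 1
#' and a warning is raised.
#'
#' @param counts Raw count tibble (`guide_id` + samples).
#' @param design A [screen_design()].
#' @param pseudocount Raw-scale pseudocount, default 0.5.
#' @param dispersion_floor Lower bound on the dispersion, default 0.01.
#' @return A tibble `guide_id`, `log2fc`, `base_mean`, `p_value`, `padj`
#'   (guide statistics, one row per guide).
#' @export
nb_test <- function(counts, design, pseudocount = 0.5, dispersion_floor = 0.01) {
  stopifnot(inherits(design, "screen_design"))
  norm_tbl <- normalize_by_control(counts, design)
  raw <- .count_matrix(counts)
  lfc <- guide_log2fc(norm_tbl, design, pseudocount)
  bm <- base_mean(norm_tbl)
  R <- nrow(design$pairs)
  n_g <- nrow(raw)

  if (R < 2L) {
    warn("Fewer than 2 replicates: dispersion cannot be estimated, p-values set to 1.")
    p <- rep(1, n_g)
  } else {
    sf <- .median_ratio_sf(raw)
    norm_mr <- sweep(raw, 2L, sf, "/")
    groups <- ifelse(colnames(raw) %in% design$pairs$before, "before", "after")
    phi <- .mom_dispersion(raw, norm_mr, groups, floor = dispersion_floor)
    # per-replicate log2 ratios, median-centered to remove the shared
    # normalization offset of the single-control size factors
    lr <- vapply(seq_len(R), function(r) {
      b <- design$pairs$before[r]
      a <- design$pairs$after[r]
      l <- log2((raw[, a] / sf[[a]] + pseudocount) / (raw[, b] / sf[[b]] + pseudocount))
      l - median(l)
    }, numeric(n_g))
    lr <- matrix(lr, nrow = n_g)
    effect <- rowMeans(lr)
    # per-sample variance of log(count): Poisson plug-in + dispersion
    vlog <- (1 / (raw + pseudocount)) + phi
    var_l2 <- vapply(seq_len(R), function(r) {
      b <- design$pairs$before[r]
      a <- design$pairs$after[r]
      (vlog[, a] + vlog[, b]) / log(2)^2
    }, numeric(n_g))
    var_l2 <- matrix(var_l2, nrow = n_g)
    se <- sqrt(rowSums(var_l2)) / R
    z <- effect / se
    p <- 2 * pnorm(-abs(z))
    p[rowSums(raw) == 0] <- 1
    p[!is.finite(p)] <- 1
  }
  res <- tibble(
    guide_id = rownames(raw),
    log2fc = lfc$log2fc,
    base_mean = bm$base_mean,
    p_value = p
  )
  res$padj <- p.adjust(res$p_value, method = "BH")
  res
}

#' Full guide-level statistics for one screen
#'
#' Convenience wrapper running [normalize_by_control()], [guide_log2fc()],
#' [base_mean()] and [nb_test()] and returning the merged guide statistics
#' table.
#'
#' @inheritParams nb_test
#' @return A tibble `guide_id`, `log2fc`, `base_mean`, `p_value`, `padj`.
#' @export
guide_stats <- function(counts, design, pseudocount = 0.5) {
  nb_test(counts, design, pseudocount = pseudocount)
}

#' Read counts and a design from TSV
#'
#' Counts: first column `guide_id`, one column per sample. Design: columns
#' `sample_id`, `condition`, `replicate`.
#'
#' @param counts_path,design_path File paths.
#' @return A list with `counts` (tibble) and `design` ([screen_design()]).
#' @export
read_screen <- function(counts_path, design_path) {
  counts <- readr::read_tsv(counts_path, show_col_types = FALSE)
  design <- screen_design(readr::read_tsv(design_path, show_col_types = FALSE))
  list(counts = counts, design = design)
}

#' Write guide statistics as CSV
#'
#' Deposited-table-like layout: guide_id, log2FC, baseMean, pvalue, padj.
#'
#' @param stats Guide statistics tibble from [guide_stats()].
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_guide_stats <- function(stats, path) {
  out <- stats |>
    rename(log2FC = "log2fc", baseMean = "base_mean", pvalue = "p_value")
  readr::write_csv(out, path)
  invisible(path)
}
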
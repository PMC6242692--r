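#' Per-gene nested linear model for capsid-production defects
#'
#' The log2 fold-change of a guide after library transduction is strongly
#' driven by the guide's effect on cell growth. To ask whether silencing a
#' given gene reduces the production of functional phage particles beyond its
#' growth effect, an ordinary least-squares model
#' `y = b0 + b1 * x + b2 * z` is fitted over all retained coding-strand
#' guides, where `y` is the transduction log2FC, `x` the growth-screen log2FC
#' and `z` indicates the focal gene's guides. The gene effect is tested by the
#' nested F comparison against `y = b0 + b1 * x` (1 numerator degree of
#' freedom); `b2` ("estimate") is negative when silencing the gene decreases
#' functional-capsid output.
#'
#' @param y Numeric vector: transduction log2FC per guide.
#' @param x Numeric vector: growth-screen log2FC per guide.
#' @param z Logical vector: `TRUE` for the focal gene's guides.
#' @return A list of class `gene_model_fit` with `estimate`, `F`, `p_value`,
#'   `df_residual`, `n`, `coefficients`.
#' @export
fit_gene_model <- function(y, x, z) {
  keep <- complete.cases(y, x, z)
  y <- y[keep]
  x <- x[keep]
  z <- as.logical(z[keep])
  n <- length(y)
  if (all(z) || !any(z)) abort("`z` must mark a non-empty proper subset of guides.")
  if (n < 6L) abort("Need at least 3 more guides than parameters (n >= 6).")

  X_red <- cbind(1, x)
  X_full <- cbind(1, x, as.numeric(z))
  fit_red <- stats::lm.fit(X_red, y)
  rank_full <- qr(X_full)$rank
  if (rank_full < 3L) {
    warn("Collinear predictors: gene indicator is confounded with growth log2FC; p set to 1.")
    return(structure(
      list(
        estimate = NA_real_, F = 0, p_value = 1,
        df_residual = n - 2L, n = n,
        coefficients = c(fit_red$coefficients, gene = NA_real_)
      ),
      class = "gene_model_fit"
    ))
  }
  fit_full <- stats::lm.fit(X_full, y)
  rss_red <- sum(fit_red$residuals^2)
  rss_full <- sum(fit_full$residuals^2)
  df2 <- n - 3L
  delta <- max(rss_red - rss_full, 0)
  tol <- 1e-12 * max(sum(y^2), 1)
  Fstat <- if (rss_full <= tol) {
    if (delta <= tol) 0 else Inf # noiseless fits: no gene effect vs exact one
  } else {
    delta / (rss_full / df2)
  }
  p <- if (is.infinite(Fstat)) 0 else pf(Fstat, 1, df2, lower.tail = FALSE)
  structure(
    list(
      estimate = unname(fit_full$coefficients[3L]),
      F = Fstat, p_value = p, df_residual = df2, n = n,
      coefficients = setNames(
        fit_full$coefficients, c("(Intercept)", "growth_log2fc", "gene")
      )
    ),
    class = "gene_model_fit"
  )
}

#' @export
print.gene_model_fit <- function(x, ...) {
  cat(sprintf(
    "<gene_model_fit> estimate = %.4g, F = %.4g, p = %.3g (n = %d)\n",
    x$estimate, x$F, x$p_value, x$n
  ))
  invisible(x)
}

#' @rdname fit_gene_model
#' @param x A `gene_model_fit`.
#' @param ... Unused.
#' @export
tidy.gene_model_fit <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients)
  )
}

#' @rdname fit_gene_model
#' @export
glance.gene_model_fit <- function(x, ...) {
  tibble(
    estimate = x$estimate, statistic = x$F, p.value = x$p_value,
    df.residual = x$df_residual, nobs = x$n
  )
}

#' Genome-wide host-factor screen for functional capsid production
#'
#' Runs [fit_gene_model()] for every gene with at least `min_guides` guides,
#' adjusts p-values by Benjamini-Hochberg across all tested genes, and calls a
#' hit whenever FDR < `fdr_threshold`. `direction` is `decreases_capsids` for
#' negative estimates.
#'
#' Guides lacking a growth-screen log2FC are dropped from every fit.
#'
#' @param guide_genes Character vector: target gene per guide (`NA` for
#'   intergenic/control guides, which only contribute to the background fit).
#' @param y Transduction log2FC per guide.
#' @param x Growth-screen log2FC per guide.
#' @param min_guides Minimum guides per tested gene, default 1.
#' @param fdr_threshold Hit threshold on BH-adjusted p, default 0.05.
#' @return A tibble of class `transduction_stats`: `gene`, `n_guides`,
#'   `estimate`, `F`, `p_value`, `fdr`, `hit`, `direction`, ranked by
#'   `estimate`.
#' @export
host_factor_screen <- function(guide_genes, y, x, min_guides = 1L,
                               fdr_threshold = 0.05) {
  keep <- !is.na(y) & !is.na(x)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " guide(s) without both screens' log2FC dropped from fits.")
  }
  guide_genes <- guide_genes[keep]
  y <- y[keep]
  x <- x[keep]
  genes <- table(guide_genes[!is.na(guide_genes)])
  genes <- names(genes)[genes >= min_guides]
  fits <- purrr::map(genes, function(gn) {
    z <- !is.na(guide_genes) & guide_genes == gn
    fit_gene_model(y, x, z)
  })
  res <- tibble(
    gene = genes,
    n_guides = vapply(genes, function(gn) sum(guide_genes == gn, na.rm = TRUE), integer(1)),
    estimate = vapply(fits, `[[`, numeric(1), "estimate"),
    F = vapply(fits, `[[`, numeric(1), "F"),
    p_value = vapply(fits, `[[`, numeric(1), "p_value")
  )
  res$fdr <- p.adjust(res$p_value, method = "BH")
  res |>
    mutate(
      hit = .data$fdr < fdr_threshold,
      direction = if_else(
        .data$estimate < 0, "decreases_capsids", "increases_capsids",
        missing = NA_character_
      )
    ) |>
    arrange(.data$estimate)
}

#' Global regression of transduction on growth fold-changes
#'
#' Simple OLS of transduction log2FC on growth log2FC with the F-test of the
#' slope; used for the QC plot showing that packaged-particle output tracks
#' guide fitness.
#'
#' @param y Transduction log2FC per guide.
#' @param x Growth log2FC per guide.
#' @return A list `slope`, `intercept`, `F`, `df`, `p_value`, `n`.
#' @export
global_fitness_regression <- function(y, x) {
  keep <- complete.cases(y, x)
  y <- y[keep]
  x <- x[keep]
  if (length(y) < 3L) abort("Need at least 3 guides.")
  if (var(x) == 0) abort("Constant growth log2FC: slope is undefined.")
  n <- length(y)
  fit <- stats::lm.fit(cbind(1, x), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  df <- n - 2L
  Fstat <- if (rss <= 1e-12 * max(tss, 1)) Inf else (tss - rss) / (rss / df)
  p <- if (is.infinite(Fstat)) 0 else pf(Fstat, 1, df, lower.tail = FALSE)
  list(
    slope = unname(fit$coefficients[2L]), intercept = unname(fit$coefficients[1L]),
    F = Fstat, df = df, p_value = p, n = n
  )
}

#' Write transduction statistics as CSV
#'
#' Deposited-table-like layout: gene, sgRNAs, estimate, p-value, FDR.
#'
#' @param stats Tibble from [host_factor_screen()].
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_transduction_stats <- function(stats, path) {
  out <- stats |>
    select(
      "gene",
      sgRNAs = "n_guides", "estimate", `p-value` = "p_value", FDR = "fdr",
      "hit", "direction"
    )
  readr::write_csv(out, path)
  invisible(path)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
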
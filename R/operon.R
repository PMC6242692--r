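#' Classify genes of one transcription unit under polar silencing
#'
#' dCas9 silencing is polar: blocking one gene of a transcription unit (TU)
#' also represses every downstream gene. Depletion of a gene's guides can
#' therefore be caused by a downstream essential gene rather than the gene
#' itself. Within each maximal run of consecutive depleted (observed) genes,
#' only the most downstream gene is confidently essential; the genes above it
#' in the run are potentially essential (their depletion may be entirely
#' polar). A non-depleted gene lying upstream of a depleted gene -- with no
#' depleted gene in between, which the run structure guarantees for the nearest
#' one -- indicates an internal promoter driving the downstream gene, since
#' the polar effect through the non-depleted gene evidently does not reach it.
#'
#' Genes with no coding-strand guides are "unobserved" (`NA` flag): they are
#' skipped when scanning downstream, never called themselves, and noted in the
#' evidence.
#'
#' @param tu_genes Character vector of gene names, 5'->3' in transcription
#'   order.
#' @param depleted Logical vector aligned with `tu_genes` (`NA` = unobserved).
#' @param tu_id TU identifier carried into the output.
#' @return A tibble `gene`, `tu_id`, `depleted`, `category`, `evidence` with
#'   `category` one of `confidently_essential`, `potentially_essential`,
#'   `internal_promoter_candidate`, `non_essential`, `unobserved`.
#' @export
#'
#' @examples
#' classify_tu(c("gA", "gB"), c(TRUE, FALSE)) # gA confidently essential
#' classify_tu(c("gA", "gB"), c(TRUE, TRUE)) # gA potentially, gB confidently
#' classify_tu(c("gA", "gB"), c(FALSE, TRUE)) # gA internal-promoter candidate
classify_tu <- function(tu_genes, depleted, tu_id = "TU") {
  if (length(tu_genes) != length(depleted)) {
    abort("`tu_genes` and `depleted` must have the same length.")
  }
  n <- length(tu_genes)
  obs_idx <- which(!is.na(depleted))
  obs_flags <- depleted[obs_idx]
  category <- rep("unobserved", n)
  evidence <- rep("no coding-strand guides", n)

  for (pos in seq_along(obs_idx)) {
    i <- obs_idx[pos]
    downstream <- if (pos < length(obs_idx)) obs_idx[(pos + 1L):length(obs_idx)] else integer(0)
    next_obs <- if (length(downstream)) downstream[1L] else NA_integer_
    if (isTRUE(depleted[i])) {
      if (!is.na(next_obs) && isTRUE(depleted[next_obs])) {
        category[i] <- "potentially_essential"
        evidence[i] <- paste0(
          "depletion may be polar via downstream depleted gene ", tu_genes[next_obs]
        )
      } else {
        category[i] <- "confidently_essential"
        evidence[i] <- if (is.na(next_obs)) {
          "depleted; most downstream observed gene of its unit"
        } else {
          paste0("depleted; next observed gene ", tu_genes[next_obs], " is not depleted")
        }
      }
    } else {
      dn_depleted <- downstream[which(depleted[downstream])]
      if (length(dn_depleted)) {
        category[i] <- "internal_promoter_candidate"
        evidence[i] <- paste0(
          "not depleted despite depleted downstream gene ",
          tu_genes[dn_depleted[1L]],
          "; internal promoter likely drives downstream expression"
        )
      } else {
        category[i] <- "non_essential"
        evidence[i] <- "not depleted, no depleted gene downstream"
      }
    }
  }
  if (any(is.na(depleted))) {
    gap <- which(is.na(depleted))
    evidence[gap] <- "no coding-strand guides; skipped in downstream scan"
  }
  tibble(
    gene = tu_genes, tu_id = tu_id, depleted = depleted,
    category = category, evidence = evidence
  )
}

#' Operon-aware classification of all depleted genes
#'
#' Applies [classify_tu()] to every transcription unit. Depleted genes outside
#' any TU are treated as monocistronic and called confidently essential.
#' Genes belonging to several TUs are classified under each and flagged in the
#' evidence.
#'
#' @param tus TU table (columns `tu_id`, `gene`, `rank`, `strand`), e.g. from
#'   [tu_table()].
#' @param depleted_flags A data frame with columns `gene` and `depleted`
#'   (logical, `NA` = unobserved), e.g. from [call_essential()] renamed, or a
#'   named logical vector.
#' @return A list with `calls` (tibble of per-gene [classify_tu()] rows) and
#'   `summary` (tibble: `n_confident`, `n_uncertain`, `n_internal_promoter`,
#'   `n_depleted`).
#' @export
classify_genome <- function(tus, depleted_flags) {
  if (is.data.frame(depleted_flags)) {
    flags <- setNames(depleted_flags$depleted, depleted_flags$gene)
  } else {
    flags <- depleted_flags
  }
  tus <- as_tibble(tus)
  known <- tus$gene %in% names(flags)
  if (!all(known)) {
    abort(paste0(
      "Genes referenced by TUs but missing from flags: ",
      paste(head(tus$gene[!known], 5L), collapse = ", ")
    ))
  }
  calls <- tus |>
    group_by(.data$tu_id) |>
    group_map(function(df, key) {
      df <- df |> arrange(.data$rank)
      classify_tu(df$gene, unname(flags[df$gene]), tu_id = key$tu_id)
    }) |>
    bind_rows()

  # monocistronic treatment for genes not in any TU
  orphan <- setdiff(names(flags), tus$gene)
  if (length(orphan)) {
    calls <- bind_rows(
      calls,
      tibble(
        gene = orphan, tu_id = NA_character_, depleted = unname(flags[orphan]),
        category = case_when(
          is.na(flags[orphan]) ~ "unobserved",
          flags[orphan] ~ "confidently_essential",
          TRUE ~ "non_essential"
        ),
        evidence = if_else(
          !is.na(flags[orphan]) & flags[orphan],
          "depleted, monocistronic", "monocistronic"
        )
      )
    )
  }
  multi <- calls |> count(.data$gene) |> filter(.data$n > 1L)
  if (nrow(multi)) {
    calls <- calls |>
      mutate(evidence = if_else(
        .data$gene %in% multi$gene,
        paste0(.data$evidence, "; gene belongs to multiple TUs"),
        .data$evidence
      ))
  }
  summary <- tibble(
    n_confident = sum(calls$category == "confidently_essential"),
    n_uncertain = sum(calls$category == "potentially_essential"),
    n_internal_promoter = sum(calls$category == "internal_promoter_candidate"),
    n_depleted = sum(calls$depleted, na.rm = TRUE)
  )
  list(calls = calls, summary = summary)
}

#' Attribute potentially essential calls to downstream genes
#'
#' Annotates every potentially essential gene with the downstream depleted
#' gene(s) of its transcription unit that can explain its depletion through the
#' polar effect; when a label column of essential / near-essential genes is
#' supplied, the attribution is restricted to labelled downstream genes and a
#' polar false-positive fraction is computed among depleted genes lacking a
#' label of their own.
#'
#' @param calls `calls` tibble from [classify_genome()].
#' @param labels Optional data frame with columns `gene` and `essential_like`
#'   (logical; essential or near-essential by external annotation).
#' @return A list with `attribution` (tibble `gene`, `tu_id`, `explained_by`)
#'   and `summary` (tibble `n_unlabeled_depleted`, `n_explained_by_polar`,
#'   `polar_fraction`; all `NA` when no labels are given).
#' @export
polar_attribution <- function(calls, labels = NULL) {
  lab <- NULL
  if (!is.null(labels)) {
    lab <- setNames(as.logical(labels$essential_like), labels$gene)
  }
  per_tu <- calls |>
    filter(!is.na(.data$tu_id)) |>
    group_by(.data$tu_id) |>
    group_map(function(df, key) {
      out <- df |> filter(.data$category == "potentially_essential")
      if (nrow(out) == 0L) return(NULL)
      out$explained_by <- vapply(match(out$gene, df$gene), function(i) {
        dn <- df$gene[seq_len(nrow(df)) > i & !is.na(df$depleted) & df$depleted]
        if (!is.null(lab)) {
          labelled <- dn[!is.na(lab[dn]) & lab[dn]]
          if (length(labelled)) dn <- labelled
        }
        paste(dn, collapse = ",")
      }, character(1))
      out$tu_id <- key$tu_id
      out |> select("gene", "tu_id", "explained_by")
    }) |>
    bind_rows()
  if (is.null(lab)) {
    summary <- tibble(
      n_unlabeled_depleted = NA_integer_, n_explained_by_polar = NA_integer_,
      polar_fraction = NA_real_
    )
  } else {
    depleted <- calls |> filter(!is.na(.data$depleted) & .data$depleted)
    unlabeled <- depleted |>
      filter(is.na(lab[.data$gene]) | !lab[.data$gene])
    explained <- unlabeled |>
      filter(
        .data$category == "potentially_essential",
        .data$gene %in% per_tu$gene[per_tu$explained_by != ""]
      )
    # explained only when a labelled downstream gene exists
    lab_explained <- per_tu |>
      filter(.data$gene %in% unlabeled$gene) |>
      mutate(has_lab = purrr::map_lgl(
        strsplit(.data$explained_by, ","),
        function(gs) any(!is.na(lab[gs]) & lab[gs])
      )) |>
      filter(.data$has_lab)
    summary <- tibble(
      n_unlabeled_depleted = nrow(unlabeled),
      n_explained_by_polar = nrow(lab_explained),
      polar_fraction = nrow(lab_explained) / max(nrow(unlabeled), 1L)
    )
  }
  list(attribution = per_tu, summary = summary)
}
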
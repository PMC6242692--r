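# The ten 5-nt PAM-proximal seeds associated with dCas9 toxicity in E. coli
# (consumed as a constant; bad-seed discovery itself is out of scope).
BAD_SEEDS <- c(
  "AGGAA", "TAGGA", "ACCCA", "TTGGA", "TATAG",
  "GAGGC", "AAAGG", "GGGAT", "TAGAC", "GTCCT"
)

#' QC configuration for guide filtering
#'
#' Bundles the guide exclusion rules: toxic 5-nt PAM-proximal seeds, the two
#' PAM-proximal off-target match lengths (9 nt against promoter regions, 11 nt
#' against coding strands), the promoter window around start codons, read-count
#' floors and multi-target handling.
#'
#' @param bad_seeds Character vector of 5-mers whose presence as the 5
#'   PAM-proximal spacer bases flags a guide as toxic.
#' @param k_promoter PAM-proximal match length for the promoter off-target
#'   rule (default 9).
#' @param k_coding PAM-proximal match length for the coding-strand off-target
#'   rule (default 11).
#' @param promoter_window `c(upstream, downstream)` in nt around the first base
#'   of the start codon, measured in transcription direction (default 100, 20).
#' @param min_total_reads Guides with fewer summed raw reads across all samples
#'   are dropped (default 20).
#' @param min_base_mean Phage screens additionally drop guides whose mean
#'   control-normalized count is below this (default 10).
#' @param drop_multi_target Drop guides with more than one perfect target site
#'   from gene-level analyses (default `TRUE`); they remain available for the
#'   separate multi-target enrichment analysis.
#'
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(bad_seeds = BAD_SEEDS,
                      k_promoter = 9L,
                      k_coding = 11L,
                      promoter_window = c(100L, 20L),
                      min_total_reads = 20L,
                      min_base_mean = 10,
                      drop_multi_target = TRUE) {
  if (any(nchar(bad_seeds) != 5L)) abort("All bad seeds must be 5-mers.")
  if (!(k_promoter <= k_coding && k_coding <= 20L && k_promoter >= 1L)) {
    abort("Need 1 <= k_promoter <= k_coding <= 20.")
  }
  if (any(promoter_window < 0L) || length(promoter_window) != 2L) {
    abort("`promoter_window` must be two non-negative lengths.")
  }
  structure(
    list(
      bad_seeds = toupper(bad_seeds), k_promoter = as.integer(k_promoter),
      k_coding = as.integer(k_coding),
      promoter_window = as.integer(promoter_window),
      min_total_reads = min_total_reads, min_base_mean = min_base_mean,
      drop_multi_target = isTRUE(drop_multi_target)
    ),
    class = "qc_config"
  )
}

#' Bad-seed flag
#'
#' `TRUE` when the 5 PAM-proximal spacer bases (positions 16--20, read 5'->3')
#' are one of the configured toxic seeds.
#'
#' @param spacer Character vector of 20-nt spacers (or a guide tibble with a
#'   `spacer` column).
#' @param config A [qc_config()].
#' @return Logical vector.
#' @export
has_bad_seed <- function(spacer, config = qc_config()) {
  if (is.data.frame(spacer)) spacer <- spacer$spacer
  substr(toupper(spacer), 16L, 20L) %in% config$bad_seeds
}

# All PAM-adjacent k-mers in a genome, both strands, as one table.
# Columns: kmer (5'->3' on strand), strand, kmer_start/kmer_end/midpoint on the
# forward axis, site_start (start the full 20-nt window would have).
pam_adjacent_kmers <- function(g, k) {
  L <- g$length
  s2 <- .scan_seq(g)
  ext <- function(start, len) {
    if (length(start) == 0L) return(character(0))
    substring(s2, start, start + len - 1L)
  }

  # + strand: GG at (j, j+1); PAM = [j-1, j+1]; kmer = [j-1-k, j-2]
  gg <- .regex_starts(s2, "GG")
  if (g$circular) {
    gg <- gg[gg <= L]
    ks <- .mod1(gg - 1L - k, L)
    plus <- tibble(
      kmer = ext(ks, k), strand = "+",
      kmer_start = ks, kmer_end = .mod1(ks + k - 1L, L),
      midpoint = .mod1(ks + (k - 1L) %/% 2L, L),
      site_start = .mod1(gg - 21L, L)
    )
  } else {
    keep <- gg - 1L - k >= 1L & gg + 1L <= L
    gg <- gg[keep]
    ks <- gg - 1L - k
    plus <- tibble(
      kmer = ext(ks, k), strand = "+",
      kmer_start = ks, kmer_end = ks + k - 1L,
      midpoint = ks + (k - 1L) %/% 2L,
      site_start = gg - 21L
    )
  }

  # - strand: CC at (j, j+1); PAM = [j, j+2]; kmer on minus = revcomp of
  # forward [j+3, j+k+2]
  cc <- .regex_starts(s2, "CC")
  if (g$circular) {
    cc <- cc[cc <= L]
    ks <- .mod1(cc + 3L, L)
    fwd <- ext(ks, k)
    minus <- tibble(
      kmer = if (length(ks)) revcomp(fwd) else character(0), strand = "-",
      kmer_start = ks, kmer_end = .mod1(ks + k - 1L, L),
      midpoint = .mod1(ks + (k - 1L) %/% 2L, L),
      site_start = ks
    )
  } else {
    keep <- cc + k + 2L <= L
    cc <- cc[keep]
    ks <- cc + 3L
    fwd <- ext(ks, k)
    minus <- tibble(
      kmer = if (length(ks)) revcomp(fwd) else character(0), strand = "-",
      kmer_start = ks, kmer_end = ks + k - 1L,
      midpoint = ks + (k - 1L) %/% 2L,
      site_start = ks
    )
  }
  bind_rows(plus, minus)
}

# Promoter windows on the forward axis: 100 nt upstream through 20 nt
# downstream of the first base of the start codon, in transcription direction.
promoter_windows <- function(genes, config, genome_length = Inf) {
  up <- config$promoter_window[1L]
  down <- config$promoter_window[2L]
  genes <- as_gene_table(genes)
  w <- genes |>
    mutate(
      win_left = if_else(.data$strand == "+", .data$left - up, .data$right - down + 1L),
      win_right = if_else(.data$strand == "+", .data$left + down - 1L, .data$right + up)
    )
  if (is.finite(genome_length)) {
    # clamp rather than wrap; windows crossing the origin are rare in practice
    w <- w |> mutate(
      win_left = pmax(.data$win_left, 1L),
      win_right = pmin(.data$win_right, as.integer(genome_length))
    )
  }
  w |>
    filter(.data$win_left <= .data$win_right) |>
    select("gene", "strand", "win_left", "win_right")
}

# midpoint-in-interval test via IRanges
.points_in <- function(points, left, right) {
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start = points, width = 1L),
    IRanges::IRanges(start = left, end = right)
  )
  tibble(point_row = S4Vectors::queryHits(hits), iv_row = S4Vectors::subjectHits(hits))
}

#' Off-target QC flags
#'
#' Flags guides whose PAM-proximal bases have additional perfect PAM-adjacent
#' matches in sensitive locations: `offtarget_promoter` when the `k_promoter`
#' PAM-proximal bases match (either orientation) with the match midpoint
#' inside any gene's promoter window; `offtarget_coding` when the `k_coding`
#' PAM-proximal bases match inside a gene body in the orientation that
#' hybridizes the sgRNA to that gene's coding strand. The guide's own
#' on-target site never counts.
#'
#' @param guides Guide library tibble (columns `guide_id`, `spacer`, `start`,
#'   `strand`, `is_control`).
#' @param g The `crispri_genome`.
#' @param genes Gene table.
#' @param config A [qc_config()].
#' @return A tibble `guide_id`, `offtarget_promoter`, `offtarget_coding`.
#'   Control guides are tested too (their matches have no on-target site to
#'   exclude).
#' @export
offtarget_flags <- function(guides, g, genes, config = qc_config()) {
  guides <- as_tibble(guides)
  genes <- as_gene_table(genes)

  flag_from_hits <- function(k, restrict) {
    km <- pam_adjacent_kmers(g, k)
    suffix <- substr(toupper(guides$spacer), 21L - k, 20L)
    joined <- tibble(
      guide_row = seq_len(nrow(guides)),
      kmer = suffix,
      own_start = guides$start,
      own_strand = guides$strand
    ) |>
      inner_join(km, by = "kmer", relationship = "many-to-many") |>
      filter(
        is.na(.data$own_start) |
          !(.data$site_start == .data$own_start & .data$strand == .data$own_strand)
      )
    restrict(joined)
  }

  # promoter rule: midpoint in any promoter window, either orientation
  pw <- promoter_windows(genes, config, genome_length = g$length)
  prom_rows <- flag_from_hits(config$k_promoter, function(joined) {
    if (nrow(joined) == 0L) return(integer(0))
    inwin <- .points_in(joined$midpoint, pw$win_left, pw$win_right)
    unique(joined$guide_row[unique(inwin$point_row)])
  })

  # coding rule: midpoint inside a gene body, match strand opposite the gene
  # strand (so the sgRNA hybridizes to the gene's coding strand)
  cod_rows <- flag_from_hits(config$k_coding, function(joined) {
    if (nrow(joined) == 0L) return(integer(0))
    inb <- .points_in(joined$midpoint, genes$left, genes$right)
    if (nrow(inb) == 0L) return(integer(0))
    ok <- joined$strand[inb$point_row] != genes$strand[inb$iv_row]
    unique(joined$guide_row[unique(inb$point_row[ok])])
  })

  tibble(
    guide_id = guides$guide_id,
    offtarget_promoter = seq_len(nrow(guides)) %in% prom_rows,
    offtarget_coding = seq_len(nrow(guides)) %in% cod_rows
  )
}

#' Read-count QC flags
#'
#' Growth mode flags guides whose total raw reads across all samples fall
#' below `min_total_reads`. Phage mode additionally flags guides whose base
#' mean (mean control-normalized count across samples) falls below
#' `min_base_mean`.
#'
#' @param counts A count matrix tibble: `guide_id` column plus one non-negative
#'   integer column per sample.
#' @param config A [qc_config()].
#' @param mode `"growth"` or `"phage"`.
#' @param control_guide_id Row used for normalization in phage mode.
#' @return A tibble `guide_id`, `low_reads`, `low_base_mean`.
#' @export
count_filters <- function(counts, config = qc_config(), mode = c("growth", "phage"),
                          control_guide_id = CONTROL_GUIDE_ID) {
  mode <- match.arg(mode)
  counts <- as_tibble(counts)
  m <- as.matrix(counts[setdiff(names(counts), "guide_id")])
  if (nrow(m) == 0L || ncol(m) == 0L) abort("Empty count matrix.")
  total <- rowSums(m)
  low_reads <- total < config$min_total_reads
  low_base_mean <- rep(FALSE, nrow(m))
  if (mode == "phage") {
    ci <- match(control_guide_id, counts$guide_id)
    if (is.na(ci)) abort("Control guide not found in count matrix; cannot normalize.")
    if (any(m[ci, ] == 0)) abort("Control guide has zero reads in at least one sample.")
    # size factors = control counts rescaled to unit geometric mean, so the
    # base mean stays on the read-count scale the threshold refers to
    ctrl <- m[ci, ]
    sf <- ctrl / exp(mean(log(ctrl)))
    norm <- sweep(m, 2L, sf, "/")
    low_base_mean <- rowMeans(norm) < config$min_base_mean
  }
  tibble(guide_id = counts$guide_id, low_reads = low_reads, low_base_mean = low_base_mean)
}

#' Apply all guide QC filters
#'
#' Combines the bad-seed, off-target, multi-target and read-count rules into a
#' retained library plus an auditable per-guide report. The non-targeting
#' control guide is always retained (it is the normalization factor, so the
#' pipeline cannot proceed without it).
#'
#' @param library Guide library tibble (see [build_guide_library()]).
#' @param g The `crispri_genome`.
#' @param genes Gene table.
#' @param counts Optional count matrix tibble for the read-count rules; `NULL`
#'   skips them.
#' @param config A [qc_config()].
#' @param mode Passed to [count_filters()].
#' @return A list with `retained` (filtered library tibble), `report`
#'   (per-guide flag tibble with a `retained` column) and `summary` (one row
#'   per exclusion reason with guide counts).
#' @export
apply_qc <- function(library, g, genes, counts = NULL, config = qc_config(),
                     mode = "growth") {
  library <- as_tibble(library)
  if (!any(library$is_control)) {
    abort("Library has no control guide; downstream normalization is impossible.")
  }
  flags <- tibble(
    guide_id = library$guide_id,
    bad_seed = has_bad_seed(library$spacer, config),
    multi_target = if (config$drop_multi_target) {
      !library$is_control & library$n_perfect_sites > 1L
    } else {
      rep(FALSE, nrow(library))
    }
  )
  ot <- offtarget_flags(library, g, genes, config)
  flags <- left_join(flags, ot, by = "guide_id")
  if (!is.null(counts)) {
    cf <- count_filters(counts, config, mode = mode)
    flags <- left_join(flags, cf, by = "guide_id") |>
      mutate(
        low_reads = tidyr::replace_na(.data$low_reads, FALSE),
        low_base_mean = tidyr::replace_na(.data$low_base_mean, FALSE)
      )
  } else {
    flags$low_reads <- FALSE
    flags$low_base_mean <- FALSE
  }
  reason_cols <- c(
    "bad_seed", "offtarget_promoter", "offtarget_coding",
    "multi_target", "low_reads", "low_base_mean"
  )
  any_flag <- Reduce(`|`, lapply(reason_cols, function(cn) flags[[cn]]))
  flags$retained <- !any_flag | library$is_control
  summary <- tibble(
    reason = c(reason_cols, "retained"),
    n = unname(c(
      vapply(reason_cols, function(cn) sum(flags[[cn]]), integer(1)),
      sum(flags$retained)
    ))
  )
  list(
    retained = library[flags$retained, , drop = FALSE],
    report = flags,
    summary = summary
  )
}

#' Write a QC report
#'
#' One CSV row per guide with all flags, plus a JSON summary of exclusion
#' counts.
#'
#' @param qc Result of [apply_qc()].
#' @param csv_path,json_path Output paths.
#' @return `csv_path`, invisibly.
#' @export
write_qc_report <- function(qc, csv_path, json_path = NULL) {
  readr::write_csv(qc$report, csv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      as.list(setNames(qc$summary$n, qc$summary$reason)),
      json_path,
      auto_unbox = TRUE
    )
  }
  invisible(csv_path)
}
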
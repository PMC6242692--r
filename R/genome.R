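#' Construct a genome object
#'
#' A genome is a single DNA sequence over the strict alphabet ACGT (ambiguity
#' codes are rejected), optionally circular. Bacterial chromosomes are circular
#' by default, so protospacer windows may wrap across the origin.
#'
#' All coordinates in this package are 1-based and inclusive on the forward
#' strand axis, as in GFF.
#'
#' @param sequence A single character string (or `Biostrings::DNAString`) over
#'   ACGT, length > 23.
#' @param id Identifier for the sequence.
#' @param circular Is the molecule circular? Default `TRUE`.
#'
#' @return An object of class `crispri_genome`: a list with elements `id`,
#'   `seq` (uppercase character scalar), `length` and `circular`.
#' @export
#'
#' @examples
#' g <- genome(paste(rep("ACGT", 10), collapse = ""), id = "toy")
#' g$length
genome <- function(sequence, id = "genome", circular = TRUE) {
  seq <- toupper(as.character(sequence))
  if (length(seq) != 1L) abort("`sequence` must be a single string.")
  if (nchar(seq) <= 23L) abort("Genome must be longer than 23 nt.")
  if (grepl("[^ACGT]", seq)) {
    abort("Genome sequence contains characters outside ACGT (ambiguity codes are not supported).")
  }
  structure(
    list(id = id, seq = seq, length = nchar(seq), circular = isTRUE(circular)),
    class = "crispri_genome"
  )
}

#' @export
print.crispri_genome <- function(x, ...) {
  cat(sprintf(
    "<crispri_genome> %s: %d bp, %s\n", x$id, x$length,
    if (x$circular) "circular" else "linear"
  ))
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()]; the first record is used.
#'
#' @param path Path to a FASTA file.
#' @inheritParams genome
#' @return A `crispri_genome`.
#' @export
read_genome <- function(path, circular = TRUE) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) abort("No sequences found in FASTA file.")
  genome(as.character(set[[1L]]), id = names(set)[[1L]], circular = circular)
}

#' Write a genome to FASTA
#'
#' @param x A `crispri_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(x, path) {
  set <- Biostrings::DNAStringSet(setNames(x$seq, x$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read or validate a gene table
#'
#' Genes live on the genome's forward axis with 1-based inclusive `left` and
#' `right` (`left <= right` always, regardless of strand). `strand` gives the
#' coding orientation; optional columns carry an essentiality gold standard and
#' transcription-unit (operon) membership.
#'
#' @param x A data frame with columns `gene`, `left`, `right`, `strand`
#'   and optionally `essential` (logical), `tu_id`, `tu_rank`.
#' @return A validated tibble with all six optional/required columns.
#' @export
as_gene_table <- function(x) {
  x <- as_tibble(x)
  req <- c("gene", "left", "right", "strand")
  miss <- setdiff(req, names(x))
  if (length(miss)) abort(paste0("Gene table is missing columns: ", paste(miss, collapse = ", ")))
  if (!all(x$strand %in% c("+", "-"))) abort("Gene strand must be '+' or '-'.")
  if (any(x$left > x$right)) abort("Gene table has left > right.")
  if (!"essential" %in% names(x)) x$essential <- NA
  if (!"tu_id" %in% names(x)) x$tu_id <- NA_character_
  if (!"tu_rank" %in% names(x)) x$tu_rank <- NA_integer_
  # within one TU the rank must be unique and the strand shared
  chk <- x |>
    filter(!is.na(.data$tu_id)) |>
    group_by(.data$tu_id) |>
    summarise(
      dup = anyDuplicated(.data$tu_rank) > 0L,
      mixed = n_distinct(.data$strand) > 1L,
      .groups = "drop"
    )
  if (any(chk$dup)) abort("Duplicate tu_rank within a transcription unit.")
  if (any(chk$mixed)) abort("Genes within one transcription unit must share a strand.")
  x |> select("gene", "left", "right", "strand", "essential", "tu_id", "tu_rank")
}

#' Read a gene table from TSV
#'
#' @param path TSV with columns gene, left, right, strand and optionally
#'   essential, tu_id, tu_rank.
#' @return A tibble (see [as_gene_table()]).
#' @export
read_gene_table <- function(path) {
  as_gene_table(readr::read_tsv(path, show_col_types = FALSE))
}

#' Derive the transcription-unit table from a gene table
#'
#' @param genes A gene table (see [as_gene_table()]).
#' @return A tibble with columns `tu_id`, `gene`, `rank`, `strand`, ordered
#'   5' to 3' in transcription direction within each unit. Genes without a
#'   `tu_id` are returned as singleton units named after the gene.
#' @export
tu_table <- function(genes) {
  genes <- as_gene_table(genes)
  genes |>
    mutate(
      tu_id = if_else(is.na(.data$tu_id), paste0("TU_", .data$gene), .data$tu_id),
      tu_rank = if_else(is.na(.data$tu_rank), 1L, as.integer(.data$tu_rank))
    ) |>
    arrange(.data$tu_id, .data$tu_rank) |>
    transmute(.data$tu_id, .data$gene, rank = .data$tu_rank, .data$strand)
}

# Doubled-sequence view used for circular scans: windows that wrap the origin
# are read from the second copy and reported modulo genome length.
.scan_seq <- function(g) if (g$circular) paste0(g$seq, g$seq) else g$seq

.mod1 <- function(pos, L) ((pos - 1L) %% L) + 1L

# All start positions of a lookahead regex (overlapping matches allowed).
.regex_starts <- function(subject, pattern) {
  m <- gregexpr(paste0("(?=", pattern, ")"), subject, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

#' Enumerate all protospacers in a genome
#'
#' Scans both strands for 20-nt windows whose 3' end is immediately followed by
#' an NGG protospacer-adjacent motif (PAM) on the same strand. For circular
#' genomes windows may wrap across the origin.
#'
#' @param g A `crispri_genome`.
#' @return A tibble with one row per site: `start` (forward-axis 1-based
#'   coordinate of the leftmost base of the 20-nt window), `strand` (the
#'   protospacer strand, i.e. the strand whose 5'->3' sequence equals the
#'   spacer), `spacer` (20 nt, 5'->3' on `strand`), `pam` (3 nt, 5'->3' on
#'   `strand`) and `pam_start` (forward-axis coordinate of the PAM base nearest
#'   the spacer). Sorted by `start`, then strand.
#' @export
#'
#' @examples
#' g <- genome("AAAAAAAAAAAAAAAAAAAAAAGGTT", circular = FALSE)
#' find_protospacers(g)
find_protospacers <- function(g) {
  stopifnot(inherits(g, "crispri_genome"))
  L <- g$length
  s2 <- .scan_seq(g)

  # + strand: spacer [i, i+19], PAM [i+20, i+22] with GG at [i+21, i+22]
  gg <- .regex_starts(s2, "GG")
  i_plus <- gg - 21L
  if (g$circular) {
    keep <- gg <= L              # each GG origin counted once
    i_plus <- .mod1(i_plus[keep], L)
  } else {
    i_plus <- i_plus[i_plus >= 1L & gg + 1L <= L]
  }

  # - strand: forward layout CCN + window; CC at [j, j+1], spacer [j+3, j+22]
  cc <- .regex_starts(s2, "CC")
  if (g$circular) {
    cc <- cc[cc <= L]
    i_minus <- .mod1(cc + 3L, L)
    j_minus <- cc
  } else {
    keep <- cc + 22L <= L
    j_minus <- cc[keep]
    i_minus <- j_minus + 3L
  }

  ext <- function(start, len) {
    if (length(start) == 0L) return(character(0))
    substring(s2, start, start + len - 1L)
  }
  pos2 <- function(i) i

  plus <- tibble(
    start = i_plus, strand = "+",
    spacer = ext(pos2(i_plus), 20L),
    pam = ext(pos2(i_plus) + 20L, 3L),
    pam_start = .mod1(i_plus + 20L, L)
  )
  minus_fwd <- ext(pos2(i_minus), 20L)
  minus_pam_fwd <- if (g$circular) {
    ext(.mod1(i_minus - 3L, L), 3L)
  } else {
    ext(i_minus - 3L, 3L)
  }
  minus <- tibble(
    start = i_minus, strand = "-",
    spacer = if (length(i_minus)) revcomp(minus_fwd) else character(0),
    pam = if (length(i_minus)) revcomp(minus_pam_fwd) else character(0),
    pam_start = .mod1(i_minus - 1L, L)
  )
  out <- bind_rows(plus, minus)
  # wrapped windows near the origin must still be read contiguously: for
  # circular genomes the doubled string already guarantees this because all
  # extraction positions are in [1, L] and windows extend at most 22 nt past L.
  out |> arrange(.data$start, .data$strand)
}

#' Find PAM-proximal matches of a spacer in a genome
#'
#' Locates every site, on either strand, where the `k` PAM-proximal bases of
#' `spacer` (its 3'-terminal `k` nt, the bases nearest the PAM) match exactly
#' and are immediately followed by an NGG PAM on the matching strand. With
#' `k = 20` this is the set of perfect target sites. The guide's own on-target
#' site is included; callers exclude it when looking for off-targets.
#'
#' @param spacer A 20-nt spacer (5'->3').
#' @param k Number of PAM-proximal bases that must match, 1--20.
#' @param g A `crispri_genome`.
#' @return A tibble with columns `strand`, `kmer_start`, `kmer_end`
#'   (forward-axis bounds of the matched k-mer), `midpoint` (forward-axis
#'   midpoint of the matched k-mer, used for interval containment tests) and
#'   `site_start` (forward-axis start the full 20-nt window would have; may
#'   fall outside the sequence for linear genomes when `k < 20`, reported
#'   modulo length for circular ones).
#' @export
match_pam_proximal <- function(spacer, k, g) {
  stopifnot(inherits(g, "crispri_genome"))
  spacer <- toupper(spacer)
  if (nchar(spacer) != 20L) abort("`spacer` must be exactly 20 nt.")
  if (grepl("[^ACGT]", spacer)) abort("`spacer` must be over ACGT.")
  if (k < 1L || k > 20L) abort("`k` must be between 1 and 20.")
  L <- g$length
  s2 <- .scan_seq(g)
  kmer <- substr(spacer, 21L - k, 20L)

  # + strand: kmer at [m, m+k-1], PAM NGG at [m+k, m+k+2]
  pat_plus <- paste0(kmer, "[ACGT]GG")
  m <- .regex_starts(s2, pat_plus)
  if (g$circular) m <- m[m <= L] else m <- m[m + k + 2L <= L]

  # - strand: forward sequence reads CC N revcomp(kmer); match at f means the
  # kmer occupies forward [f+3, f+k+2] on the minus strand
  pat_minus <- paste0("CC[ACGT]", revcomp(kmer))
  f <- .regex_starts(s2, pat_minus)
  if (g$circular) f <- f[f <= L] else f <- f[f + k + 2L <= L]

  mk_mid <- function(a, b) (a + b) %/% 2L
  plus <- tibble(
    strand = "+",
    kmer_start = if (g$circular) .mod1(m, L) else m,
    kmer_end = if (g$circular) .mod1(m + k - 1L, L) else m + k - 1L,
    midpoint = if (g$circular) .mod1(mk_mid(m, m + k - 1L), L) else mk_mid(m, m + k - 1L),
    site_start = if (g$circular) .mod1(m + k - 20L, L) else m + k - 20L
  )
  minus <- tibble(
    strand = "-",
    kmer_start = if (g$circular) .mod1(f + 3L, L) else f + 3L,
    kmer_end = if (g$circular) .mod1(f + k + 2L, L) else f + k + 2L,
    midpoint = if (g$circular) .mod1(mk_mid(f + 3L, f + k + 2L), L) else mk_mid(f + 3L, f + k + 2L),
    site_start = if (g$circular) .mod1(f + 3L, L) else f + 3L
  )
  bind_rows(plus, minus) |> arrange(.data$kmer_start, .data$strand)
}

#' Count perfect target sites of a spacer
#'
#' Number of genomic positions (both strands) where the full 20-nt spacer
#' matches exactly with an NGG PAM immediately 3'.
#'
#' @inheritParams match_pam_proximal
#' @return A non-negative integer.
#' @export
count_perfect_sites <- function(spacer, g) {
  nrow(match_pam_proximal(spacer, 20L, g))
}

#' Spacer midpoint of a site
#'
#' The forward-axis midpoint used for gene containment: the 10th base of the
#' 20-nt forward-axis window, for either strand.
#'
#' @param start Forward-axis start(s) of 20-nt windows.
#' @param L Genome length (for circular wrapping); `Inf` disables wrapping.
#' @return Integer vector of midpoints.
#' @keywords internal
spacer_midpoint <- function(start, L = Inf) {
  mid <- start + 9L
  if (is.finite(L)) mid <- .mod1(mid, as.integer(L))
  mid
}

#' Annotate guides with their target gene and strand relationship
#'
#' Assigns each guide the gene whose `[left, right]` interval contains the
#' spacer midpoint (ties broken by smallest `left`, then gene name). The sgRNA
#' hybridizes to the strand opposite its protospacer strand;
#' `targets_coding` is `TRUE` when that hybridized strand is the gene's coding
#' (sense) strand, i.e. when the protospacer strand differs from the gene
#' strand. Transcription of such genes is efficiently blocked by dCas9.
#'
#' @param guides A tibble with at least `start` and `strand` (protospacer
#'   strand) columns; control guides (`is_control == TRUE`) are left
#'   unannotated.
#' @param genes A gene table (see [as_gene_table()]).
#' @param genome_length Genome length for midpoint wrapping (optional).
#' @return `guides` with columns `target_gene` (character, `NA` when
#'   intergenic) and `targets_coding` (logical, `NA` when intergenic) added
#'   or replaced.
#' @export
annotate_guides <- function(guides, genes, genome_length = Inf) {
  genes <- as_gene_table(genes)
  guides <- as_tibble(guides)
  if (!"is_control" %in% names(guides)) guides$is_control <- FALSE
  mid <- spacer_midpoint(guides$start, genome_length)
  ok <- which(!is.na(mid))
  hits <- IRanges::findOverlaps(
    IRanges::IRanges(start = mid[ok], width = 1L),
    IRanges::IRanges(start = genes$left, end = genes$right)
  )
  cand <- tibble(
    guide_row = ok[S4Vectors::queryHits(hits)],
    gene_row = S4Vectors::subjectHits(hits)
  ) |>
    mutate(
      left = genes$left[.data$gene_row],
      gene = genes$gene[.data$gene_row],
      gene_strand = genes$strand[.data$gene_row]
    ) |>
    arrange(.data$guide_row, .data$left, .data$gene) |>
    distinct(.data$guide_row, .keep_all = TRUE)

  guides$target_gene <- NA_character_
  guides$targets_coding <- NA
  guides$target_gene[cand$guide_row] <- cand$gene
  guides$targets_coding[cand$guide_row] <-
    guides$strand[cand$guide_row] != cand$gene_strand
  guides$target_gene[guides$is_control] <- NA_character_
  guides$targets_coding[guides$is_control] <- NA
  guides
}

#' Build a guide library tibble from sites
#'
#' Completes a site tibble into a guide library: ids, 5-nt PAM-proximal seed,
#' perfect-site counts, gene annotation and the non-targeting control guide.
#'
#' @param sites A tibble from [find_protospacers()] (or a subset of it).
#' @param g The `crispri_genome` the sites came from.
#' @param genes Optional gene table for annotation.
#' @param add_control Append the non-targeting control guide? Default `TRUE`.
#' @return A guide library tibble with columns `guide_id`, `spacer`, `start`,
#'   `strand`, `pam_start`, `seed5`, `n_perfect_sites`, `is_control`,
#'   `target_gene`, `targets_coding`.
#' @export
build_guide_library <- function(sites, g, genes = NULL, add_control = TRUE) {
  lib <- as_tibble(sites) |>
    mutate(
      guide_id = sprintf("g%06d_%s", .data$start, .data$strand),
      seed5 = substr(.data$spacer, 16L, 20L),
      is_control = FALSE
    )
  # every perfect match of a spacer next to NGG is itself an enumerated
  # protospacer, so per-spacer site counts are duplicate tallies over the
  # full enumeration (equivalent to count_perfect_sites, but one genome scan)
  all_spacers <- find_protospacers(g)$spacer
  tally <- table(all_spacers)
  lib$n_perfect_sites <- as.integer(tally[lib$spacer])
  lib$n_perfect_sites[is.na(lib$n_perfect_sites)] <- 0L
  if (add_control) {
    ctrl <- tibble(
      start = NA_integer_, strand = NA_character_,
      spacer = CONTROL_SPACER, pam = NA_character_, pam_start = NA_integer_,
      guide_id = CONTROL_GUIDE_ID,
      seed5 = substr(CONTROL_SPACER, 16L, 20L),
      is_control = TRUE,
      n_perfect_sites = if (is.na(tally[CONTROL_SPACER])) 0L else as.integer(tally[CONTROL_SPACER])
    )
    lib <- bind_rows(lib, ctrl)
  }
  if (!is.null(genes)) {
    lib <- annotate_guides(lib, genes, genome_length = g$length)
  } else {
    lib$target_gene <- NA_character_
    lib$targets_coding <- NA
  }
  lib |>
    select(
      "guide_id", "spacer", "start", "strand", "pam_start", "seed5",
      "n_perfect_sites", "is_control", "target_gene", "targets_coding"
    )
}

#' Write / read a guide library CSV
#'
#' Column layout mirrors a deposited guide table: guide_id, spacer, position
#' (start), ori (protospacer strand), coding (targets_coding), gene.
#'
#' @param lib A guide library tibble.
#' @param path CSV path.
#' @return `path` (write) or a tibble (read).
#' @export
write_guide_library <- function(lib, path) {
  readr::write_csv(lib, path)
  invisible(path)
}

#' @rdname write_guide_library
#' @export
read_guide_library <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
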
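# Independent brute-force oracles used across the test files. These are
# deliberately written as plain loops over string positions so they share no
# code path with the package implementation.

rc_chr <- function(x) {
  vapply(x, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

random_genome_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# circular-aware substring on the forward axis
circ_sub <- function(s, from, len, circular) {
  L <- nchar(s)
  if (!circular) {
    if (from < 1 || from + len - 1 > L) return(NA_character_)
    return(substring(s, from, from + len - 1))
  }
  idx <- ((from - 1 + seq_len(len) - 1) %% L) + 1
  paste(vapply(idx, function(i) substring(s, i, i), character(1)), collapse = "")
}

# every 20-nt window followed by NGG, both strands, by exhaustive scan
oracle_protospacers <- function(s, circular) {
  L <- nchar(s)
  rows <- list()
  for (i in seq_len(L)) {
    win <- circ_sub(s, i, 23, circular)
    if (!is.na(win) && substring(win, 22, 23) == "GG") {
      rows[[length(rows) + 1]] <- data.frame(
        start = i, strand = "+", spacer = substring(win, 1, 20),
        stringsAsFactors = FALSE
      )
    }
    win2 <- circ_sub(s, i - 3, 23, circular)
    if (!is.na(win2) && substring(win2, 1, 2) == "CC") {
      rows[[length(rows) + 1]] <- data.frame(
        start = i, strand = "-", spacer = rc_chr(substring(win2, 4, 23)),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(start = integer(0), strand = character(0), spacer = character(0)))
  }
  out <- out[order(out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

# sites where the k PAM-proximal bases of `spacer` match next to NGG
oracle_suffix_sites <- function(spacer, k, s, circular) {
  L <- nchar(s)
  kmer <- substring(spacer, 21 - k, 20)
  rows <- list()
  for (i in seq_len(L)) {
    # + strand: kmer at i .. i+k-1, NGG at i+k .. i+k+2
    win <- circ_sub(s, i, k + 3, circular)
    if (!is.na(win) && substring(win, 1, k) == kmer &&
      substring(win, k + 2, k + 3) == "GG") {
      rows[[length(rows) + 1]] <- data.frame(
        strand = "+", kmer_start = i, stringsAsFactors = FALSE
      )
    }
    # - strand: forward reads CCN + rc(kmer) starting at i-3
    win2 <- circ_sub(s, i - 3, k + 3, circular)
    if (!is.na(win2) && substring(win2, 1, 2) == "CC" &&
      substring(win2, 4, k + 3) == rc_chr(kmer)) {
      rows[[length(rows) + 1]] <- data.frame(
        strand = "-", kmer_start = i, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(strand = character(0), kmer_start = integer(0)))
  }
  out <- out[order(out$kmer_start, out$strand), ]
  rownames(out) <- NULL
  out
}

# gene containing a point, smallest-left then name tie-break
oracle_assign_gene <- function(mid, genes) {
  hit <- genes[genes$left <= mid & genes$right >= mid, ]
  if (nrow(hit) == 0) return(NA_character_)
  hit <- hit[order(hit$left, hit$gene), ]
  hit$gene[1]
}

# two-sided Fisher p by full hypergeometric enumeration (minimum likelihood)
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b
  n <- c + d
  k <- a + c
  lo <- max(0, k - n)
  hi <- min(k, m)
  x <- lo:hi
  logp <- dhyper(x, m, n, k, log = TRUE)
  obs <- dhyper(a, m, n, k, log = TRUE)
  sum(exp(logp[logp <= obs + 1e-7]))
}

# OLS + nested F by explicit normal equations and RSS ratio
oracle_ols_nested <- function(y, x, z) {
  X_full <- cbind(1, x, as.numeric(z))
  X_red <- cbind(1, x)
  beta_full <- solve(t(X_full) %*% X_full, t(X_full) %*% y)
  beta_red <- solve(t(X_red) %*% X_red, t(X_red) %*% y)
  rss_full <- sum((y - X_full %*% beta_full)^2)
  rss_red <- sum((y - X_red %*% beta_red)^2)
  df2 <- length(y) - 3
  Fs <- (rss_red - rss_full) / (rss_full / df2)
  list(
    estimate = beta_full[3], F = Fs,
    p = pf(Fs, 1, df2, lower.tail = FALSE)
  )
}

# Benjamini-Hochberg by the textbook formula
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# operon rule applied gene by gene, independent of the package implementation:
# confident iff depleted and the nearest observed downstream gene is not
# depleted; potentially iff depleted and it is; internal-promoter candidate iff
# clean with any observed depleted gene downstream; else non-essential.
oracle_classify <- function(flags) {
  n <- length(flags)
  out <- rep("unobserved", n)
  for (i in seq_len(n)) {
    if (is.na(flags[i])) next
    down <- if (i < n) flags[(i + 1):n] else logical(0)
    down <- down[!is.na(down)]
    if (flags[i]) {
      out[i] <- if (length(down) && down[1]) "potentially_essential" else "confidently_essential"
    } else {
      out[i] <- if (any(down)) "internal_promoter_candidate" else "non_essential"
    }
  }
  out
}

# small toy gene table
toy_genes <- function() {
  tibble::tibble(
    gene = c("gA", "gB", "gC"),
    left = c(101L, 401L, 701L),
    right = c(300L, 600L, 900L),
    strand = c("+", "-", "+")
  )
}

# fast small simulation config for tests; ... overrides the small defaults
small_sim <- function(seed, ...) {
  args <- utils::modifyList(
    list(
      seed = seed, genome_length = 90000L, n_genes = 60L,
      library_size = 2000L, depth = 2e5
    ),
    list(...)
  )
  do.call(sim_config, args)
}
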
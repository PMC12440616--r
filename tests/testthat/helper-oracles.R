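# Independent oracles and small generators used across the suite.
# These deliberately use different algorithms from the package code
# (position-by-position enumeration instead of regex matching; a plain
# dynamic-programming matrix instead of Biostrings) so that agreement is
# meaningful.

random_residues <- function(len, alphabet = c("A", "C", "D", "E", "F", "G",
                                              "H", "I", "K", "L", "M", "N",
                                              "P", "Q", "R", "S", "T", "V",
                                              "W", "Y")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Brute-force cleavage-site enumerator: walk the sequence, expand each
# basic residue into its maximal K/R run, list every adjacent motif pair
# (including the glycine-extended pair), and keep runs with >= 1
# configured motif. Mirrors the maximal-run resolution rule by
# construction rather than by regex.
oracle_cleavage_sites <- function(residues,
                                  motifs = c("KK", "RK", "KR", "RR",
                                             "GK", "GR")) {
  ch <- strsplit(residues, "", fixed = TRUE)[[1]]
  n <- length(ch)
  is_basic <- ch %in% c("K", "R")
  out <- list()
  i <- 1L
  while (i <= n) {
    if (!is_basic[i]) {
      i <- i + 1L
      next
    }
    j <- i
    while (j < n && is_basic[j + 1L]) j <- j + 1L
    g <- i > 1L && ch[i - 1L] == "G"
    pairs <- character(0)
    if (j > i) {
      pairs <- vapply(i:(j - 1L), function(k) paste0(ch[k], ch[k + 1L]),
                      character(1))
    }
    if (g) pairs <- c(paste0("G", ch[i]), pairs)
    if (any(pairs %in% motifs)) {
      out[[length(out) + 1L]] <- data.frame(
        start = if (g) i - 1L else i, end = j,
        basic_run = paste(ch[i:j], collapse = ""), amide_donor = g,
        stringsAsFactors = FALSE)
    }
    i <- j + 1L
  }
  if (length(out)) {
    do.call(rbind, out)
  } else {
    data.frame(start = integer(), end = integer(),
               basic_run = character(), amide_donor = logical(),
               stringsAsFactors = FALSE)
  }
}

# Quadratic affine-gap Smith-Waterman (gap of length L costs
# open + extend * L), independent of the alignment library.
oracle_sw_score <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- length(A)
  n <- length(B)
  H <- E <- F <- matrix(0, m + 1L, n + 1L)
  best <- 0
  for (i in 2:(m + 1L)) {
    for (j in 2:(n + 1L)) {
      E[i, j] <- max(H[i, j - 1L] - gap_open - gap_extend,
                     E[i, j - 1L] - gap_extend)
      F[i, j] <- max(H[i - 1L, j] - gap_open - gap_extend,
                     F[i - 1L, j] - gap_extend)
      H[i, j] <- max(0, H[i - 1L, j - 1L] + mat[A[i - 1L], B[j - 1L]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# Reconstruction check: pre-signal region + inter-site segments + consumed
# site residues, concatenated in order, must reproduce the input exactly.
reconstructs <- function(residues, signal_end = 0L,
                         config = scanner_config()) {
  sites <- find_cleavage_sites(residues, config)
  cfg <- config
  cfg$allow_terminal_peptide <- TRUE  # need the trailing segment to rebuild
  pep <- segment_peptides(residues, sites, signal_end, cfg)
  pieces <- rbind(
    if (signal_end > 0L) data.frame(start = 1L, end = signal_end),
    sites[sites$start > signal_end, c("start", "end")],
    pep[, c("start", "end")])
  pieces <- pieces[order(pieces$start), , drop = FALSE]
  rebuilt <- paste(substring(residues, pieces$start, pieces$end),
                   collapse = "")
  identical(rebuilt, residues)
}

# Write a small two-family sequence set with high within-family and low
# between-family identity, for clustering recovery tests.
make_two_family_set <- function(n_per_family = 10L, len = 60L,
                                mutation_rate = 0.15) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M", "N",
          "P", "Q", "S", "T", "V", "W", "Y")
  template <- function() sample(aa, len, replace = TRUE)
  mutate <- function(tpl) {
    flip <- runif(len) < mutation_rate
    tpl[flip] <- sample(aa, sum(flip), replace = TRUE)
    paste(tpl, collapse = "")
  }
  t1 <- template()
  t2 <- template()
  seqs <- c(vapply(seq_len(n_per_family), function(i) mutate(t1), character(1)),
            vapply(seq_len(n_per_family), function(i) mutate(t2), character(1)))
  names(seqs) <- c(sprintf("famA_%02d", seq_len(n_per_family)),
                   sprintf("famB_%02d", seq_len(n_per_family)))
  seqs
}
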
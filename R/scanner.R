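# The core computation: locate prohormone-convertase cleavage sites,
# extract candidate mature peptides, annotate post-translational
# modifications (C-terminal amidation, N-terminal pyroglutamate,
# proline-protection), assign peptide families and score precursors.
#
# Site model: cleavage occurs at dibasic motifs (KK, RK, KR, RR) and at
# glycine-extended single basics (GK, GR). A site consumes the maximal run
# of K/R plus, when present, the glycine immediately preceding the run;
# that glycine is the amide donor, so the upstream peptide is flagged
# amidated. An isolated K or R with no preceding G is not a site
# (monobasic cleavage is outside the motif set). "X" never matches K, R
# or G.

DEFAULT_CLEAVAGE_MOTIFS <- c("KK", "RK", "KR", "RR", "GK", "GR")

#' Cleavage-site scanner configuration
#'
#' @param cleavage_motifs Ordered set of length-2 motifs over \{K, R, G\}
#'   (default `KK, RK, KR, RR, GK, GR`).
#' @param window Maximum candidate mature-peptide length in residues
#'   (default 20); longer segments are still emitted but do not count
#'   toward the precursor pass criterion.
#' @param min_len Minimum candidate peptide length (default 3).
#' @param require_n_motif If `TRUE`, a peptide counts only when it also
#'   carries an N-terminal motif (pyroglutamate Q start or proline at
#'   position 2) or starts directly after a cleavage site. Default
#'   `FALSE`: the N-terminal motifs are bonus evidence, not requirements.
#' @param allow_terminal_peptide Allow a segment ending at the protein
#'   C-terminus with no trailing site to count when it matches a family
#'   motif (default `TRUE`).
#' @return A list of class `neuropep_scanner_config`.
#' @export
scanner_config <- function(cleavage_motifs = DEFAULT_CLEAVAGE_MOTIFS,
                           window = 20L, min_len = 3L,
                           require_n_motif = FALSE,
                           allow_terminal_peptide = TRUE) {
  window <- as.integer(window)
  min_len <- as.integer(min_len)
  if (min_len < 1L || window < min_len) {
    np_usage_error("need window >= min_len >= 1")
  }
  bad <- cleavage_motifs[nchar(cleavage_motifs) != 2L |
                         grepl("[^KRG]", cleavage_motifs)]
  if (length(bad)) {
    np_usage_error(sprintf("cleavage motifs must be length-2 strings over K/R/G: %s",
                           paste(bad, collapse = ", ")))
  }
  structure(list(cleavage_motifs = unique(cleavage_motifs),
                 window = window, min_len = min_len,
                 require_n_motif = isTRUE(require_n_motif),
                 allow_terminal_peptide = isTRUE(allow_terminal_peptide)),
            class = "neuropep_scanner_config")
}

#' Locate prohormone cleavage sites
#'
#' Scans left to right for maximal runs of basic residues (K/R). A run is
#' a cleavage site iff at least one of its adjacent residue pairs —
#' including the pair formed with an immediately preceding glycine — is a
#' configured motif. A qualifying site consumes the whole basic run; when
#' the residue immediately before the run is G, that glycine is consumed
#' too and flagged as the amide donor. Sites are therefore maximal and
#' non-overlapping by construction.
#'
#' @param residues Amino-acid string (signal-trimming is handled by
#'   [segment_peptides()], which ignores sites inside the signal region).
#' @param config A [scanner_config()].
#' @return Data frame with columns `start`, `end` (1-based inclusive span
#'   of the consumed residues, including the donor G when present),
#'   `basic_run` (the K/R run) and `amide_donor` (logical).
#' @export
find_cleavage_sites <- function(residues, config = scanner_config()) {
  empty <- data.frame(start = integer(), end = integer(),
                      basic_run = character(), amide_donor = logical(),
                      stringsAsFactors = FALSE)
  m <- gregexpr("G?[KR]+", residues)[[1]]
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  motifs <- config$cleavage_motifs
  out_start <- integer(0); out_end <- integer(0)
  out_run <- character(0); out_amide <- logical(0)
  for (k in seq_along(starts)) {
    s <- starts[k]
    txt <- substr(residues, s, s + lens[k] - 1L)
    g_present <- substr(txt, 1L, 1L) == "G"
    run <- if (g_present) substr(txt, 2L, nchar(txt)) else txt
    run_start <- if (g_present) s + 1L else s
    # adjacent pairs inside the run, plus the G+first pair when present
    pairs <- character(0)
    if (nchar(run) >= 2L) {
      pairs <- substring(run, seq_len(nchar(run) - 1L), seq.int(2L, nchar(run)))
    }
    if (g_present) pairs <- c(paste0("G", substr(run, 1L, 1L)), pairs)
    if (!any(pairs %in% motifs)) next
    out_start <- c(out_start, if (g_present) s else run_start)
    out_end <- c(out_end, run_start + nchar(run) - 1L)
    out_run <- c(out_run, run)
    out_amide <- c(out_amide, g_present)
  }
  data.frame(start = out_start, end = out_end, basic_run = out_run,
             amide_donor = out_amide, stringsAsFactors = FALSE)
}

#' Default neuropeptide family motif table
#'
#' C-terminal family patterns (1-3 residues, `X` a wildcard) matched in
#' table order against the mature peptide C-terminus together with its
#' amidation state. The GLWamide pattern is simplified to X-L-W/amidated
#' (the leading-glycine preference of canonical GLWamides is recorded here
#' but not required); LW_peptide is the non-amidated L-W class.
#'
#' @return Data frame with columns `name`, `c_terminal_pattern`,
#'   `amidation_required`.
#' @export
default_family_table <- function() {
  data.frame(
    name = c("RFamide", "GLWamide", "PRXamide", "LW_peptide",
             "KVamide", "FRamide"),
    c_terminal_pattern = c("RF", "XLW", "PRX", "LW", "KV", "FR"),
    amidation_required = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

# Match a 1-3 residue C-terminal pattern (X wildcard) against a mature
# peptide. A literal pattern residue never matches an X in the peptide.
matches_c_pattern <- function(mature, pattern) {
  k <- nchar(pattern)
  n <- nchar(mature)
  if (k > n) return(FALSE)
  tail_res <- strsplit(substr(mature, n - k + 1L, n), "", fixed = TRUE)[[1]]
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  all(pat == "X" | (pat == tail_res & tail_res != "X"))
}

#' Assign a peptide to a neuropeptide family
#'
#' Returns the first family (in table order) whose C-terminal pattern
#' matches the mature peptide and whose required amidation state equals
#' the peptide's, else `"unassigned"`.
#'
#' @param mature Mature peptide string.
#' @param amidated Logical amidation flag of the peptide.
#' @param family_table A table as from [default_family_table()].
#' @return A family label (character scalar).
#' @export
assign_family <- function(mature, amidated,
                          family_table = default_family_table()) {
  for (i in seq_len(nrow(family_table))) {
    if (family_table$amidation_required[i] == amidated &&
        matches_c_pattern(mature, family_table$c_terminal_pattern[i])) {
      return(family_table$name[i])
    }
  }
  "unassigned"
}

#' Extract candidate mature peptides between cleavage sites
#'
#' Candidate segments are the maximal substrings strictly between consumed
#' site regions: from `signal_end + 1` to the first site, between
#' consecutive sites, and after the last site when
#' `allow_terminal_peptide`. Sites beginning at or before `signal_end` are
#' ignored (the signal region is not scanned). Every non-empty segment is
#' emitted; a segment *counts toward the precursor pass criterion* iff
#' `min_len <= length <= window`, its C-terminal boundary is a cleavage
#' site (or the protein terminus with a family match, when terminal
#' peptides are allowed), and — with `require_n_motif` — it additionally
#' has a pyroglutamate Q start, proline at position 2, or an N-terminal
#' site boundary.
#'
#' @param residues Amino-acid string of the precursor.
#' @param sites Site table from [find_cleavage_sites()] on `residues`.
#' @param signal_end Last residue of the signal peptide (0 for none).
#' @param config A [scanner_config()].
#' @param parent_id Precursor id recorded in the output.
#' @param family_table Family motif table for labelling.
#' @return Data frame with one row per emitted peptide: `parent_id`,
#'   `start`, `end`, `mature`, `amidated`, `pyroglu`, `xp`, `family`,
#'   `n_boundary_site`, `c_boundary_site`, `counts_toward_pass`.
#' @export
segment_peptides <- function(residues, sites, signal_end = 0L,
                             config = scanner_config(),
                             parent_id = NA_character_,
                             family_table = default_family_table()) {
  n <- nchar(residues)
  signal_end <- as.integer(signal_end)
  sites <- sites[sites$start > signal_end, , drop = FALSE]
  starts <- integer(0); ends <- integer(0)
  n_site <- logical(0); c_site <- logical(0); amid <- logical(0)
  prev_end <- signal_end
  prev_was_site <- FALSE
  for (k in seq_len(nrow(sites))) {
    a <- prev_end + 1L
    b <- sites$start[k] - 1L
    if (b >= a) {
      starts <- c(starts, a); ends <- c(ends, b)
      n_site <- c(n_site, prev_was_site)
      c_site <- c(c_site, TRUE)
      amid <- c(amid, sites$amide_donor[k])
    }
    prev_end <- sites$end[k]
    prev_was_site <- TRUE
  }
  if (config$allow_terminal_peptide && prev_end < n) {
    starts <- c(starts, prev_end + 1L); ends <- c(ends, n)
    n_site <- c(n_site, prev_was_site)
    c_site <- c(c_site, FALSE)
    amid <- c(amid, FALSE)
  }
  mature <- substring(residues, starts, ends)
  len <- ends - starts + 1L
  pyroglu <- substr(mature, 1L, 1L) == "Q"
  xp <- len >= 2L & substr(mature, 2L, 2L) == "P"
  family <- mapply(assign_family, mature, amid,
                   MoreArgs = list(family_table = family_table),
                   USE.NAMES = FALSE)
  if (!length(starts)) family <- character(0)
  counts <- len >= config$min_len & len <= config$window &
    (c_site | (config$allow_terminal_peptide & family != "unassigned"))
  if (config$require_n_motif) {
    counts <- counts & (pyroglu | xp | n_site)
  }
  data.frame(parent_id = rep(parent_id, length(starts)),
             start = starts, end = ends, mature = mature,
             amidated = amid, pyroglu = pyroglu, xp = xp,
             family = family, n_boundary_site = n_site,
             c_boundary_site = c_site, counts_toward_pass = counts,
             stringsAsFactors = FALSE)
}

#' Score a precursor from its extracted peptides
#'
#' The precursor pass criterion is the literature one: at least one
#' counting peptide. The numeric score is a convenience ranking —
#' `1.0 * n_passing + 2.0 * n_repeat_groups + 0.5 * n_modified` — whose
#' weights are this package's own (configurable) invention, not a
#' published formula. A repeat group is a set of two or more counting
#' peptides sharing their C-terminal dipeptide and amidation state (the
#' hallmark of multi-copy precursors); a modified peptide carries at least
#' one of amidation, pyroglutamate, or proline at position 2.
#'
#' @param peptides Peptide table from [segment_peptides()] for one
#'   precursor.
#' @param config A [scanner_config()] (unused weights hook).
#' @param weights Numeric vector `c(peptide, repeat_group, modified)`.
#' @return One-row data frame: `precursor_id`, `n_peptides`, `n_passing`,
#'   `n_repeat_groups`, `n_modified`, `score`, `passes`.
#' @export
score_precursor <- function(peptides, config = scanner_config(),
                            weights = c(peptide = 1.0, repeat_group = 2.0,
                                        modified = 0.5)) {
  id <- if (nrow(peptides)) peptides$parent_id[1] else NA_character_
  pass <- peptides[peptides$counts_toward_pass, , drop = FALSE]
  n_passing <- nrow(pass)
  if (n_passing) {
    len <- nchar(pass$mature)
    key <- paste(substr(pass$mature, pmax(1L, len - 1L), len), pass$amidated)
    n_repeat <- sum(table(key) >= 2L)
    n_mod <- sum(pass$amidated | pass$pyroglu | pass$xp)
  } else {
    n_repeat <- 0L
    n_mod <- 0L
  }
  score <- weights[[1]] * n_passing + weights[[2]] * n_repeat +
    weights[[3]] * n_mod
  data.frame(precursor_id = id, n_peptides = nrow(peptides),
             n_passing = n_passing, n_repeat_groups = n_repeat,
             n_modified = n_mod, score = score, passes = n_passing >= 1L,
             stringsAsFactors = FALSE)
}

#' Scan a set of precursors
#'
#' Runs [find_cleavage_sites()], [segment_peptides()] and
#' [score_precursor()] over every record. The scan starts after the
#' signal peptide when the records carry a `signal_end` column (as
#' produced by [apply_prefilter()]).
#'
#' @param records Precursor table (columns `id`, `residues`, optionally
#'   `signal_end`).
#' @param config A [scanner_config()].
#' @param family_table Family motif table.
#' @return List with `peptides` (all emitted peptides) and `scores` (one
#'   row per precursor).
#' @export
scan_precursors <- function(records, config = scanner_config(),
                            family_table = default_family_table()) {
  pep_list <- vector("list", nrow(records))
  score_list <- vector("list", nrow(records))
  se <- if (is.null(records$signal_end)) rep(0L, nrow(records)) else
    ifelse(is.na(records$signal_end), 0L, records$signal_end)
  for (i in seq_len(nrow(records))) {
    sites <- find_cleavage_sites(records$residues[i], config)
    pep <- segment_peptides(records$residues[i], sites, se[i], config,
                            parent_id = records$id[i],
                            family_table = family_table)
    sc <- score_precursor(pep, config)
    sc$precursor_id <- records$id[i]
    pep_list[[i]] <- pep
    score_list[[i]] <- sc
  }
  if (!nrow(records)) {
    empty_pep <- segment_peptides("A", find_cleavage_sites("A", config),
                                  0L, config)[0, , drop = FALSE]
    return(list(peptides = empty_pep,
                scores = score_precursor(empty_pep, config)[0, , drop = FALSE]))
  }
  list(peptides = do.call(rbind, c(pep_list, list(make.row.names = FALSE))),
       scores = do.call(rbind, c(score_list, list(make.row.names = FALSE))))
}
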
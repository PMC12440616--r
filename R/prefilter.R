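# Secretome pre-filter: restrict input proteins to putative secreted,
# domain-free candidates using parsed annotator evidence, with a crude
# built-in hydrophobic-run heuristic as the fallback when no signal-caller
# evidence is available.

HYDROPHOBIC <- c("A", "I", "L", "F", "V", "M", "W", "C")
SIGNAL_END_SET <- c("A", "G", "S", "C", "T")

#' Secretome pre-filter configuration
#'
#' @param require_signal Require a predicted signal peptide (default TRUE).
#' @param max_tm_regions Maximum allowed membrane-spanning segments outside
#'   the signal region (default 0).
#' @param exclude_domains Drop proteins with a recognized functional domain
#'   (default TRUE).
#' @param missing_evidence_policy What to do with records that have no
#'   signal-caller evidence: `"drop"`, `"keep"` (treat as signal-positive),
#'   or `"heuristic"` (default; use [heuristic_signal_peptide()]).
#' @param heuristic_window Number of N-terminal residues inspected by the
#'   fallback heuristic (default 30).
#' @param heuristic_min_hydrophobic_run Minimum hydrophobic run length the
#'   heuristic requires (default 8).
#' @return A list of class `neuropep_prefilter_config`.
#' @export
prefilter_config <- function(require_signal = TRUE,
                             max_tm_regions = 0L,
                             exclude_domains = TRUE,
                             missing_evidence_policy = c("heuristic", "drop", "keep"),
                             heuristic_window = 30L,
                             heuristic_min_hydrophobic_run = 8L) {
  missing_evidence_policy <- match.arg(missing_evidence_policy)
  heuristic_window <- as.integer(heuristic_window)
  heuristic_min_hydrophobic_run <- as.integer(heuristic_min_hydrophobic_run)
  if (heuristic_min_hydrophobic_run < 1L ||
      heuristic_window < heuristic_min_hydrophobic_run) {
    np_usage_error("need heuristic_window >= heuristic_min_hydrophobic_run >= 1")
  }
  structure(list(require_signal = isTRUE(require_signal),
                 max_tm_regions = as.integer(max_tm_regions),
                 exclude_domains = isTRUE(exclude_domains),
                 missing_evidence_policy = missing_evidence_policy,
                 heuristic_window = heuristic_window,
                 heuristic_min_hydrophobic_run = heuristic_min_hydrophobic_run),
            class = "neuropep_prefilter_config")
}

#' Fallback signal-peptide heuristic
#'
#' A deliberately crude stand-in used only when signal-caller evidence is
#' absent and the missing-evidence policy is `"heuristic"`: a sequence is
#' called signal-positive iff its first `heuristic_window` residues contain
#' a run of at least `heuristic_min_hydrophobic_run` residues from the
#' hydrophobic set \{A, I, L, F, V, M, W, C\} (the signal-peptide h-region).
#' The signal end is placed at the first small/polar residue from
#' \{A, G, S, C, T\} found 1-10 residues after the run (a typical
#' signal-peptidase -1 position), else at run end + 5; it is always clamped
#' to at most `length - 1`.
#'
#' @param residues Amino-acid string.
#' @param config A [prefilter_config()].
#' @return A list with `has_signal` (logical) and `signal_end` (integer
#'   position, `NA` when `has_signal` is `FALSE`).
#' @export
heuristic_signal_peptide <- function(residues, config = prefilter_config()) {
  ch <- strsplit(residues, "", fixed = TRUE)[[1]]
  n <- length(ch)
  w <- min(config$heuristic_window, n)
  hyd <- ch[seq_len(w)] %in% HYDROPHOBIC
  r <- rle(hyd)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= config$heuristic_min_hydrophobic_run)
  if (!length(cand)) {
    return(list(has_signal = FALSE, signal_end = NA_integer_))
  }
  run_end <- ends[cand[1]]
  probe <- seq.int(run_end + 1L, min(run_end + 10L, n))
  hit <- probe[ch[probe] %in% SIGNAL_END_SET]
  signal_end <- if (length(hit)) hit[1] else run_end + 5L
  signal_end <- max(1L, min(signal_end, n - 1L))
  list(has_signal = TRUE, signal_end = as.integer(signal_end))
}

# Collapse a list of neuropep_evidence objects into per-record columns.
merge_evidence <- function(records, evidence_tables) {
  ids <- records$id
  out <- data.frame(id = ids,
                    ev_has_signal = NA, ev_signal_end = NA_integer_,
                    ev_n_tm = NA_integer_, ev_has_domain = FALSE,
                    stringsAsFactors = FALSE)
  regions <- NULL
  for (ev in evidence_tables) {
    if (is.null(ev)) next
    stopifnot(inherits(ev, "neuropep_evidence"))
    ev <- drop_orphans(ev, ids)
    tab <- ev$table
    if (ev$source == "signal_caller") {
      m <- match(ids, tab$id)
      out$ev_has_signal <- ifelse(is.na(m), out$ev_has_signal, tab$has_signal[m])
      out$ev_signal_end <- ifelse(is.na(m), out$ev_signal_end, tab$signal_end[m])
    } else if (ev$source == "tm_caller") {
      m <- match(ids, tab$id)
      out$ev_n_tm <- ifelse(is.na(m), out$ev_n_tm, tab$n_tm_regions[m])
      regions <- ev$regions
    } else if (ev$source == "domain_scanner") {
      out$ev_has_domain <- out$ev_has_domain | ids %in% tab$id
    }
  }
  list(columns = out, tm_regions = regions)
}

#' Apply the secretome pre-filter
#'
#' Keeps a record iff it has a signal peptide (from evidence, else per the
#' missing-evidence policy), at most `max_tm_regions` membrane-spanning
#' segments outside the signal region, and (when `exclude_domains`) no
#' recognized functional domain. Membrane segments lying entirely within
#' the signal region `1..signal_end` are discounted, because several TM
#' callers report the signal peptide itself as one membrane segment.
#'
#' @param records Precursor table from [read_fasta()].
#' @param evidence List of `neuropep_evidence` objects (any subset of the
#'   four sources; may be empty).
#' @param config A [prefilter_config()].
#' @return A list with `kept` (the surviving records with a `signal_end`
#'   column for downstream trimming) and `report` (data frame `id`, `kept`
#'   0/1, `reason` in `pass`, `no_signal`, `tm`, `domain`, `no_evidence`).
#' @export
apply_prefilter <- function(records, evidence = list(),
                            config = prefilter_config()) {
  mv <- merge_evidence(records, evidence)
  ev <- mv$columns
  n <- nrow(records)
  has_signal <- logical(n)
  signal_end <- rep(NA_integer_, n)
  reason <- rep("pass", n)

  for (i in seq_len(n)) {
    if (!is.na(ev$ev_has_signal[i])) {
      has_signal[i] <- ev$ev_has_signal[i]
      signal_end[i] <- ev$ev_signal_end[i]
    } else if (!is.null(records$signal_end) && !is.na(records$signal_end[i])) {
      # records already carry a signal call (e.g. a previous prefilter run)
      has_signal[i] <- TRUE
      signal_end[i] <- records$signal_end[i]
    } else {
      policy <- config$missing_evidence_policy
      if (policy == "drop") {
        reason[i] <- "no_evidence"
        next
      } else if (policy == "keep") {
        has_signal[i] <- TRUE
        signal_end[i] <- 0L
      } else {
        h <- heuristic_signal_peptide(records$residues[i], config)
        has_signal[i] <- h$has_signal
        signal_end[i] <- h$signal_end
      }
    }
    if (config$require_signal && !has_signal[i]) {
      reason[i] <- "no_signal"
      next
    }
    # TM test; segments entirely inside the signal region are discounted
    n_tm <- ev$ev_n_tm[i]
    if (!is.na(n_tm) && !is.null(mv$tm_regions)) {
      reg <- mv$tm_regions[mv$tm_regions$id == records$id[i], , drop = FALSE]
      se <- if (is.na(signal_end[i])) 0L else signal_end[i]
      n_tm <- sum(!(reg$start >= 1L & reg$end <= se))
    }
    if (!is.na(n_tm) && n_tm > config$max_tm_regions) {
      reason[i] <- "tm"
      next
    }
    if (config$exclude_domains && isTRUE(ev$ev_has_domain[i])) {
      reason[i] <- "domain"
      next
    }
  }

  kept_idx <- which(reason == "pass")
  kept <- records[kept_idx, , drop = FALSE]
  kept$signal_end <- ifelse(is.na(signal_end[kept_idx]), 0L, signal_end[kept_idx])
  rownames(kept) <- NULL
  report <- data.frame(id = records$id,
                       kept = as.integer(reason == "pass"),
                       reason = reason, stringsAsFactors = FALSE)
  list(kept = kept, report = report)
}
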
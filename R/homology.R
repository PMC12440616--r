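# Homology-based candidate filter: remove candidates whose best alignment
# hit identifies them as a non-neuropeptide homologue. Thresholds follow
# the strict inequalities of the published rule (>30% identity,
# e-value < 0.05); hits described as neuropeptide precursors or
# uncharacterized proteins are retained via a configurable keyword
# allow-list.

#' Homology filter configuration
#'
#' @param min_identity_pct Identity threshold; a removing hit must exceed
#'   this (strict, default 30).
#' @param max_evalue E-value threshold; a removing hit must be below this
#'   (strict, default 0.05).
#' @param allow_keywords Lowercase substrings of hit descriptions that
#'   mark a hit as compatible with a neuropeptide precursor; candidates
#'   whose top hit matches any keyword are kept.
#' @param deny_on_no_keyword Remove a candidate when its qualifying top
#'   hit carries none of the keywords (default TRUE; FALSE disables
#'   removal entirely, useful for auditing).
#' @return A list of class `neuropep_homology_config`.
#' @export
homology_config <- function(min_identity_pct = 30.0, max_evalue = 0.05,
                            allow_keywords = c("neuropeptide",
                                               "preprohormone", "prohormone",
                                               "precursor", "uncharacterized",
                                               "hypothetical"),
                            deny_on_no_keyword = TRUE) {
  if (min_identity_pct < 0 || min_identity_pct > 100) {
    np_usage_error("min_identity_pct must be in [0, 100]")
  }
  if (max_evalue <= 0) np_usage_error("max_evalue must be > 0")
  structure(list(min_identity_pct = min_identity_pct,
                 max_evalue = max_evalue,
                 allow_keywords = tolower(allow_keywords),
                 deny_on_no_keyword = isTRUE(deny_on_no_keyword)),
            class = "neuropep_homology_config")
}

# Top hit for one candidate: smallest e-value, ties broken by highest
# bitscore then lexicographically smallest subject id (for determinism).
top_hit <- function(hits) {
  if (!nrow(hits)) return(NULL)
  ord <- order(hits$e_value, -hits$bitscore, hits$subject)
  hits[ord[1], , drop = FALSE]
}

#' Filter candidates by their best alignment hit
#'
#' A candidate is removed iff it has a top hit with
#' `pct_identity > min_identity_pct` and `e_value < max_evalue` whose
#' description contains no allow-list keyword (case-insensitive substring
#' match). Candidates with no hits are kept: removal requires positive
#' evidence of a non-neuropeptide homologue. Each candidate's decision
#' depends only on its own top hit.
#'
#' @param candidates Character vector of candidate ids.
#' @param hit_table A `neuropep_evidence` object of source
#'   `alignment_hits`, or its `table` data frame.
#' @param config A [homology_config()].
#' @return A list with `kept`, `removed` (character vectors) and `report`
#'   (data frame `id`, `kept`, `top_subject`, `identity`, `evalue`,
#'   `matched_keyword`, `reason`).
#' @export
filter_by_homology <- function(candidates, hit_table,
                               config = homology_config()) {
  hits <- if (inherits(hit_table, "neuropep_evidence")) hit_table$table else hit_table
  n <- length(candidates)
  report <- data.frame(id = candidates, kept = 1L,
                       top_subject = NA_character_, identity = NA_real_,
                       evalue = NA_real_, matched_keyword = NA_character_,
                       reason = "no_hit", stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    h <- top_hit(hits[hits$query == candidates[i], , drop = FALSE])
    if (is.null(h)) next
    report$top_subject[i] <- h$subject
    report$identity[i] <- h$pct_identity
    report$evalue[i] <- h$e_value
    desc <- tolower(h$description)
    kw <- config$allow_keywords[vapply(config$allow_keywords, grepl, logical(1),
                                       x = desc, fixed = TRUE)]
    if (length(kw)) report$matched_keyword[i] <- kw[1]
    qualifies <- h$pct_identity > config$min_identity_pct &&
      h$e_value < config$max_evalue
    if (qualifies && !length(kw) && config$deny_on_no_keyword) {
      report$kept[i] <- 0L
      report$reason[i] <- "non_neuropeptide_homologue"
    } else {
      report$reason[i] <- if (qualifies) "allowed_hit" else "weak_hit"
    }
  }
  list(kept = candidates[report$kept == 1L],
       removed = candidates[report$kept == 0L],
       report = report)
}
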
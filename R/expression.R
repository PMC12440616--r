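# Neuronal-expression filter: retain candidates detected in neuronal
# cell populations of a single-cell atlas, summarized as gene-by-cluster
# means. The published workflow states only that candidates were
# restricted to neuronally expressed genes; the concrete two-part rule
# here (detection in a neuronal cluster + a minimum neuronal share of the
# maximum signal) is this package's own, with both knobs exposed.

#' Expression filter configuration
#'
#' @param min_neuronal_expression Detection threshold: the maximum mean
#'   over neuronal clusters must exceed this (strict; default 0 = any
#'   detection).
#' @param min_neuronal_share Minimum ratio of the best neuronal cluster
#'   mean to the best overall cluster mean, in `[0, 1]` (default 0.5).
#' @param missing_gene_policy `"drop"` (default) or `"keep"` for
#'   candidates absent from the expression summary.
#' @return A list of class `neuropep_expression_config`.
#' @export
expression_config <- function(min_neuronal_expression = 0,
                              min_neuronal_share = 0.5,
                              missing_gene_policy = c("drop", "keep")) {
  missing_gene_policy <- match.arg(missing_gene_policy)
  if (min_neuronal_share < 0 || min_neuronal_share > 1) {
    np_usage_error("min_neuronal_share must be in [0, 1]")
  }
  structure(list(min_neuronal_expression = min_neuronal_expression,
                 min_neuronal_share = min_neuronal_share,
                 missing_gene_policy = missing_gene_policy),
            class = "neuropep_expression_config")
}

#' Filter candidates by neuronal expression
#'
#' A candidate is kept iff its expression profile exists (else the
#' missing-gene policy decides), its maximum mean over neuronal clusters
#' exceeds `min_neuronal_expression`, and the ratio of that neuronal
#' maximum to the overall maximum is at least `min_neuronal_share`.
#' All-zero profiles fail the detection test before any ratio is formed,
#' so no division by zero can occur.
#'
#' @param candidates Character vector of candidate ids (gene ids).
#' @param profiles A `neuropep_expression` object from
#'   [read_expression()].
#' @param config An [expression_config()].
#' @return A list with `kept`, `removed` and `report` (data frame `id`,
#'   `kept`, `neuronal_max`, `overall_max`, `share`, `reason`).
#' @export
filter_by_expression <- function(candidates, profiles,
                                 config = expression_config()) {
  stopifnot(inherits(profiles, "neuropep_expression"))
  mat <- profiles$means
  neuronal <- profiles$neuronal
  report <- data.frame(id = candidates, kept = 0L,
                       neuronal_max = NA_real_, overall_max = NA_real_,
                       share = NA_real_, reason = "no_profile",
                       stringsAsFactors = FALSE)
  for (i in seq_along(candidates)) {
    id <- candidates[i]
    if (!id %in% rownames(mat)) {
      if (config$missing_gene_policy == "keep") {
        report$kept[i] <- 1L
        report$reason[i] <- "no_profile_kept"
      }
      next
    }
    row <- mat[id, ]
    nmax <- if (length(neuronal)) max(row[neuronal]) else 0
    omax <- max(row)
    report$neuronal_max[i] <- nmax
    report$overall_max[i] <- omax
    if (!(nmax > config$min_neuronal_expression)) {
      report$reason[i] <- "not_neuronal"
      next
    }
    share <- nmax / omax  # omax >= nmax > 0 here
    report$share[i] <- share
    if (share >= config$min_neuronal_share) {
      report$kept[i] <- 1L
      report$reason[i] <- "pass"
    } else {
      report$reason[i] <- "low_share"
    }
  }
  list(kept = candidates[report$kept == 1L],
       removed = candidates[report$kept == 0L],
       report = report)
}
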
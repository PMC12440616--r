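# Readers and writers for every external format the pipeline touches:
# protein FASTA, annotator evidence tables (one documented dialect per
# source), gene-by-cluster expression summaries, and the tab-separated
# report tables the pipeline emits. Coordinates are 1-based inclusive
# everywhere; writers state this in a header comment line.

AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALLOWED  <- c(AA_STANDARD, "X")

EVIDENCE_SOURCES <- c("signal_caller", "tm_caller", "domain_scanner",
                      "alignment_hits")

#' Read a protein FASTA file into a precursor table
#'
#' Parses a protein FASTA file into a data frame with one row per record.
#' Multi-line sequences are concatenated, whitespace stripped and lowercase
#' residues uppercased. The record id is the first whitespace-delimited
#' token of the header; the remainder of the header becomes the
#' description.
#'
#' Residues must come from the 20 standard amino acids plus `X` (unknown).
#' `X` is permitted but never matches any cleavage or family motif
#' downstream.
#'
#' @param path Path to a FASTA file. An empty file yields a zero-row table.
#' @return A data frame with columns `id`, `description`, `residues`.
#' @section Errors:
#' * duplicate ids raise a `neuropep_duplicate_id_error`;
#' * residues outside the allowed alphabet raise a
#'   `neuropep_alphabet_error` naming the record and position.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    np_usage_error(sprintf("FASTA file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  if (!any(startsWith(lines, ">"))) {
    if (all(!nzchar(trimws(lines)))) {
      return(data.frame(id = character(), description = character(),
                        residues = character(), stringsAsFactors = FALSE))
    }
    np_parse_error(sprintf("not a FASTA file (no '>' header): %s", path))
  }
  aa <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) np_parse_error(
      sprintf("failed to parse FASTA %s: %s", path, conditionMessage(e)))
  )
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(gsub("\\s", "", as.character(aa)))

  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    np_duplicate_id_error(sprintf("duplicate record id(s): %s",
                                  paste(unique(dup), collapse = ", ")))
  }
  if (any(!nzchar(seqs))) {
    np_alphabet_error(sprintf("record '%s' has an empty sequence",
                              ids[which(!nzchar(seqs))[1]]))
  }
  bad <- regexpr(sprintf("[^%s]", paste(AA_ALLOWED, collapse = "")), seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1]
    np_alphabet_error(sprintf(
      "record '%s' contains illegal residue '%s' at position %d",
      ids[i], substr(seqs[i], bad[i], bad[i]), bad[i]))
  }
  data.frame(id = ids, description = desc, residues = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write a precursor table as FASTA
#'
#' @param records Data frame with columns `id`, `residues` and optionally
#'   `description`.
#' @param path Output path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  headers <- records$id
  if (!is.null(records$description)) {
    has_desc <- nzchar(records$description)
    headers[has_desc] <- paste(records$id[has_desc],
                               records$description[has_desc])
  }
  aa <- Biostrings::AAStringSet(setNames(records$residues, headers))
  Biostrings::writeXStringSet(aa, filepath = path, width = width)
  invisible(path)
}

# Split non-comment, non-empty lines into tab fields, keeping original
# line numbers for error reporting.
split_table_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(lines, "#")
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE),
       lineno = which(keep))
}

as_num_or_parse_error <- function(x, what, lineno) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v))) {
    np_parse_error(sprintf("line %d: %s is not numeric ('%s')",
                           lineno[which(is.na(v))[1]], what,
                           x[which(is.na(v))[1]]))
  }
  v
}

#' Parse an external annotator's output table
#'
#' Normalizes the tab-separated output of one of four external annotator
#' classes into an evidence table. One dialect per source is supported
#' (see Details); comment lines starting with `#` are skipped.
#'
#' @details Dialects:
#' \describe{
#'   \item{`signal_caller`}{columns `id`, `prediction` (`SP` or `OTHER`),
#'     `cs_position` — the residue *after which* signal-peptidase cleavage
#'     occurs (i.e. the last residue of the signal peptide); `-`, `0` or
#'     `NA` when there is no signal.}
#'   \item{`tm_caller`}{per-protein region lines with columns `id`,
#'     `region_type`, `start`, `end`; only `TMhelix` lines count as
#'     membrane-spanning segments. A protein whose lines are all
#'     `inside`/`outside` has `n_tm_regions = 0`.}
#'   \item{`domain_scanner`}{columns `id`, `accession`, further columns
#'     ignored; presence of any row for an id means the protein has a
#'     recognized domain.}
#'   \item{`alignment_hits`}{the standard 12-column tabular alignment
#'     format (`query`, `subject`, `pct_identity`, `length`, `mismatches`,
#'     `gapopens`, `qstart`, `qend`, `sstart`, `send`, `e_value`,
#'     `bitscore`) with an optional 13th subject-description column.}
#' }
#'
#' @param path Path to the table.
#' @param source One of `"signal_caller"`, `"tm_caller"`,
#'   `"domain_scanner"`, `"alignment_hits"`.
#' @return An object of class `neuropep_evidence`: a list with elements
#'   `source`, `table` (the normalized per-id data frame) and, for
#'   `tm_caller`, `regions` (membrane-spanning segment coordinates).
#' @section Errors: malformed rows raise a `neuropep_parse_error` with the
#'   offending line number; an unknown source raises a
#'   `neuropep_usage_error`.
#' @export
parse_evidence <- function(path, source) {
  if (length(source) != 1L || !source %in% EVIDENCE_SOURCES) {
    np_usage_error(sprintf("unknown evidence source '%s'; must be one of %s",
                           paste(source, collapse = ","),
                           paste(EVIDENCE_SOURCES, collapse = ", ")))
  }
  if (!file.exists(path)) {
    np_usage_error(sprintf("evidence file not found: %s", path))
  }
  tl <- split_table_lines(path)
  fields <- tl$fields
  lineno <- tl$lineno
  nf <- lengths(fields)

  need <- function(min_cols) {
    bad <- which(nf < min_cols)
    if (length(bad)) {
      np_parse_error(sprintf("line %d: expected at least %d tab-separated columns, found %d",
                             lineno[bad[1]], min_cols, nf[bad[1]]))
    }
  }
  col <- function(k) vapply(fields, function(f) f[[k]], character(1))

  regions <- NULL
  if (source == "signal_caller") {
    need(3L)
    id <- col(1); pred <- col(2); cs <- col(3)
    ok <- pred %in% c("SP", "OTHER")
    if (any(!ok)) {
      np_parse_error(sprintf("line %d: prediction must be SP or OTHER, found '%s'",
                             lineno[which(!ok)[1]], pred[which(!ok)[1]]))
    }
    end <- rep(NA_integer_, length(id))
    is_sp <- pred == "SP"
    if (any(is_sp)) {
      v <- suppressWarnings(as.integer(cs[is_sp]))
      if (any(is.na(v) | v < 1L)) {
        j <- which(is_sp)[which(is.na(v) | v < 1L)[1]]
        np_parse_error(sprintf("line %d: SP row needs a positive integer cleavage position, found '%s'",
                               lineno[j], cs[j]))
      }
      end[is_sp] <- v
    }
    tab <- data.frame(id = id, has_signal = is_sp, signal_end = end,
                      stringsAsFactors = FALSE)
  } else if (source == "tm_caller") {
    need(4L)
    id <- col(1); type <- col(2)
    start <- as_num_or_parse_error(col(3), "region start", lineno)
    end <- as_num_or_parse_error(col(4), "region end", lineno)
    is_tm <- type == "TMhelix"
    regions <- data.frame(id = id[is_tm], start = as.integer(start[is_tm]),
                          end = as.integer(end[is_tm]),
                          stringsAsFactors = FALSE)
    n_tm <- vapply(unique(id), function(i) sum(is_tm & id == i), integer(1))
    tab <- data.frame(id = unique(id), n_tm_regions = unname(n_tm),
                      stringsAsFactors = FALSE)
  } else if (source == "domain_scanner") {
    need(2L)
    id <- col(1)
    n_dom <- table(id)
    tab <- data.frame(id = names(n_dom), has_domain = TRUE,
                      n_domains = as.integer(n_dom),
                      stringsAsFactors = FALSE)
    rownames(tab) <- NULL
  } else { # alignment_hits
    need(12L)
    tab <- data.frame(
      query = col(1), subject = col(2),
      pct_identity = as_num_or_parse_error(col(3), "pct_identity", lineno),
      length = as.integer(as_num_or_parse_error(col(4), "length", lineno)),
      mismatches = as.integer(as_num_or_parse_error(col(5), "mismatches", lineno)),
      gapopens = as.integer(as_num_or_parse_error(col(6), "gapopens", lineno)),
      qstart = as.integer(as_num_or_parse_error(col(7), "qstart", lineno)),
      qend = as.integer(as_num_or_parse_error(col(8), "qend", lineno)),
      sstart = as.integer(as_num_or_parse_error(col(9), "sstart", lineno)),
      send = as.integer(as_num_or_parse_error(col(10), "send", lineno)),
      e_value = as_num_or_parse_error(col(11), "e_value", lineno),
      bitscore = as_num_or_parse_error(col(12), "bitscore", lineno),
      description = vapply(fields, function(f)
        if (length(f) >= 13L) f[[13]] else "", character(1)),
      stringsAsFactors = FALSE)
  }
  structure(list(source = source, table = tab, regions = regions),
            class = "neuropep_evidence")
}

#' Write an evidence table back out in its documented dialect
#'
#' Inverse of [parse_evidence()] for the normalized tables produced by the
#' synthetic generator, so that file-based pipeline runs can be assembled
#' entirely from generated data.
#'
#' @param evidence A `neuropep_evidence` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evidence <- function(evidence, path) {
  stopifnot(inherits(evidence, "neuropep_evidence"))
  tab <- evidence$table
  lines <- switch(evidence$source,
    signal_caller = sprintf("%s\t%s\t%s", tab$id,
                            ifelse(tab$has_signal, "SP", "OTHER"),
                            ifelse(tab$has_signal, tab$signal_end, "-")),
    tm_caller = {
      reg <- evidence$regions
      out <- character(0)
      for (i in seq_len(nrow(tab))) {
        r <- reg[reg$id == tab$id[i], , drop = FALSE]
        if (nrow(r)) {
          out <- c(out, sprintf("%s\tTMhelix\t%d\t%d", r$id, r$start, r$end))
        } else {
          out <- c(out, sprintf("%s\tinside\t1\t1", tab$id[i]))
        }
      }
      out
    },
    domain_scanner = sprintf("%s\t%s", tab$id,
                             if (is.null(tab$accession)) "PF00000" else tab$accession),
    alignment_hits = sprintf("%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3g\t%.1f\t%s",
                             tab$query, tab$subject, tab$pct_identity,
                             tab$length, tab$mismatches, tab$gapopens,
                             tab$qstart, tab$qend, tab$sstart, tab$send,
                             tab$e_value, tab$bitscore, tab$description))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-by-cluster expression summary
#'
#' Reads a tab-separated genes-by-clusters matrix of non-negative
#' expression summaries (e.g. cluster mean counts) together with a
#' two-column cluster annotation file mapping each cluster name to
#' `neuronal` or `non_neuronal`.
#'
#' @param matrix_path Tab-separated matrix; first column gene ids, header
#'   row of cluster names.
#' @param clusters_path Two-column tab-separated file `cluster<TAB>class`
#'   with class `neuronal` or `non_neuronal`; an optional header line is
#'   tolerated.
#' @return An object of class `neuropep_expression`: list with `means`
#'   (numeric matrix, genes x clusters) and `neuronal` (character vector
#'   of neuronal cluster names).
#' @section Errors: negative or non-numeric values raise a
#'   `neuropep_value_error`; matrix columns missing from the annotation
#'   raise a `neuropep_schema_error`.
#' @export
read_expression <- function(matrix_path, clusters_path) {
  for (p in c(matrix_path, clusters_path)) {
    if (!file.exists(p)) np_usage_error(sprintf("file not found: %s", p))
  }
  raw <- utils::read.delim(matrix_path, row.names = 1, check.names = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
  mat <- as.matrix(raw)
  suppressWarnings(storage.mode(mat) <- "double")
  if (any(is.na(mat))) {
    np_value_error("expression matrix contains missing or non-numeric values")
  }
  if (any(mat < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1, ]
    np_value_error(sprintf("negative expression value for gene '%s', cluster '%s'",
                           rownames(mat)[bad[1]], colnames(mat)[bad[2]]))
  }
  ann <- utils::read.delim(clusters_path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(ann) < 2L) np_schema_error("cluster annotation needs two columns")
  classes <- c("neuronal", "non_neuronal")
  if (nrow(ann) > 0L && !(ann[[2]][1] %in% classes)) ann <- ann[-1, , drop = FALSE]
  if (any(!ann[[2]] %in% classes)) {
    np_schema_error(sprintf("cluster class must be one of %s; found '%s'",
                            paste(classes, collapse = "/"),
                            ann[[2]][which(!ann[[2]] %in% classes)[1]]))
  }
  missing <- setdiff(colnames(mat), ann[[1]])
  if (length(missing)) {
    np_schema_error(sprintf("cluster(s) absent from annotation file: %s",
                            paste(missing, collapse = ", ")))
  }
  neuronal <- intersect(ann[[1]][ann[[2]] == "neuronal"], colnames(mat))
  structure(list(means = mat, neuronal = neuronal),
            class = "neuropep_expression")
}

#' Write a gene-by-cluster expression summary
#'
#' @param expression A `neuropep_expression` object.
#' @param matrix_path,clusters_path Output paths (see [read_expression()]).
#' @return Invisibly, `matrix_path`.
#' @export
write_expression <- function(expression, matrix_path, clusters_path) {
  stopifnot(inherits(expression, "neuropep_expression"))
  mat <- expression$means
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cls <- ifelse(colnames(mat) %in% expression$neuronal,
                "neuronal", "non_neuronal")
  writeLines(sprintf("%s\t%s", colnames(mat), cls), clusters_path)
  invisible(matrix_path)
}

#' Write a report table as TSV
#'
#' Writes a data frame as a tab-separated table preceded by a comment
#' line stating the package's coordinate convention (1-based inclusive)
#' and, when given, the seed of the producing run.
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param seed Optional integer seed echoed into the header.
#' @return `path`, invisibly.
#' @export
write_report <- function(df, path, seed = NULL) {
  hdr <- "# neuropep; coordinates are 1-based inclusive"
  if (!is.null(seed)) hdr <- sprintf("%s; seed=%d", hdr, as.integer(seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Match evidence rows to loaded records: rows whose id is absent from the
# record set are orphaned; warn and drop rather than error, since users
# commonly subset FASTAs.
drop_orphans <- function(evidence, ids) {
  tab <- evidence$table
  key <- if (evidence$source == "alignment_hits") tab$query else tab$id
  orphan <- !key %in% ids
  if (any(orphan)) {
    warning(sprintf("%d orphaned %s evidence row(s) ignored (ids not in input): %s",
                    sum(orphan), evidence$source,
                    paste(utils::head(unique(key[orphan]), 5), collapse = ", ")),
            call. = FALSE)
    evidence$table <- tab[!orphan, , drop = FALSE]
    if (!is.null(evidence$regions)) {
      evidence$regions <- evidence$regions[evidence$regions$id %in% ids, ,
                                           drop = FALSE]
    }
  }
  evidence
}
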
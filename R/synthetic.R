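# Synthetic secreted proteomes with ground-truth manifests: precursor
# architectures with repeated peptide copies and cleavage contexts,
# decoy proteins (random / transmembrane / domain-bearing), alignment-hit
# tables and gene-by-cluster expression summaries, so every pipeline
# stage is testable end to end without downloads or external binaries.
#
# All generation draws from R's RNG; seed with set.seed() (or use the
# `seed` argument of make_benchmark()) for reproducibility.

# Planted signal peptide recognized by the prefilter heuristic by
# construction: hydrophobic run F+L*10 (length 11 >= 8), first small
# residue after the run is S at position 14 => signal_end = 14.
SYNTH_SIGNAL <- "MKFLLLLLLLLLLSA"
SYNTH_SIGNAL_END <- 14L

# Residues used for spacers and random cores: no K/R (cannot create or
# extend cleavage sites), no G (cannot create an amide donor), and no
# hydrophobic-run builders that could fake a signal peptide.
SPACER_ALPHABET <- c("S", "T", "N", "E", "D", "P", "H", "Q", "Y")

random_string <- function(n, alphabet) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Specification of one synthetic precursor
#'
#' Describes the architecture of a planted neuropeptide precursor: a
#' signal peptide (recognized by the prefilter heuristic by
#' construction), then `n_copies` repeats of
#' `spacer + cleavage motif + peptide_core + [G if amidated] + cleavage
#' motif`, and a trailing spacer. Every planted core is flanked by
#' consumed cleavage sites, so its mature coordinates are unambiguous.
#'
#' The core must not create or merge with a planted site: no adjacent
#' basic residues, no `G` immediately before a basic, no K/R as first or
#' last residue, and no terminal `G`. Internal isolated basics (as in
#' `QFRF`) are allowed. `adversarial = TRUE` deliberately relaxes this:
#' an extra isolated basic is inserted into the core and, with
#' probability 0.25, an embedded dibasic that splits the planted peptide
#' (such cores are marked non-recoverable in the truth manifest).
#'
#' @param n_copies Number of peptide copies (>= 1).
#' @param peptide_core Mature peptide residue string.
#' @param amidated Plant a G amide donor before the basic run iff TRUE.
#' @param cleavage_motif One of the six cleavage motifs.
#' @param spacer_len_range Integer pair: spacer length bounds.
#' @param signal Plant a signal peptide (default TRUE).
#' @return A list of class `neuropep_precursor_spec`.
#' @export
precursor_spec <- function(n_copies, peptide_core, amidated,
                           cleavage_motif = "KR",
                           spacer_len_range = c(4L, 10L),
                           signal = TRUE) {
  n_copies <- as.integer(n_copies)
  if (n_copies < 1L) np_spec_error("n_copies must be >= 1")
  if (!cleavage_motif %in% DEFAULT_CLEAVAGE_MOTIFS) {
    np_spec_error(sprintf("cleavage_motif must be one of %s",
                          paste(DEFAULT_CLEAVAGE_MOTIFS, collapse = ", ")))
  }
  core <- toupper(peptide_core)
  if (grepl("[KR][KR]", core) || grepl("G[KR]", core) ||
      grepl("^[KR]|[KRG]$", core)) {
    np_spec_error(paste("peptide_core must not contain adjacent basics,",
                        "G before a basic, K/R at either end, or a",
                        "terminal G (planted boundaries would be ambiguous)"))
  }
  if (nchar(core) < 1L) np_spec_error("peptide_core must be non-empty")
  spacer_len_range <- as.integer(spacer_len_range)
  if (length(spacer_len_range) != 2L || any(spacer_len_range < 0L) ||
      spacer_len_range[1] > spacer_len_range[2]) {
    np_spec_error("spacer_len_range must be a non-decreasing pair >= 0")
  }
  if (!isTRUE(amidated) && startsWith(cleavage_motif, "G")) {
    np_spec_error(paste("a glycine-extended motif (GK/GR) would itself act",
                        "as the amide donor; non-amidated peptides need a",
                        "dibasic cleavage_motif"))
  }
  structure(list(n_copies = n_copies, peptide_core = core,
                 amidated = isTRUE(amidated),
                 cleavage_motif = cleavage_motif,
                 spacer_len_range = spacer_len_range,
                 signal = isTRUE(signal)),
            class = "neuropep_precursor_spec")
}

#' Generate one synthetic precursor with its ground truth
#'
#' @param spec A [precursor_spec()].
#' @param id Record id to assign.
#' @param adversarial If TRUE, corrupt the core as described in
#'   [precursor_spec()].
#' @return A list with `record` (one-row precursor table) and `truth`
#'   (data frame of planted peptides: `id`, `start`, `end`, `mature`,
#'   `amidated`, `recoverable`).
#' @export
make_precursor <- function(spec, id = "synthetic_precursor",
                           adversarial = FALSE) {
  stopifnot(inherits(spec, "neuropep_precursor_spec"))
  core <- spec$peptide_core
  recoverable <- TRUE
  if (adversarial && nchar(core) >= 3L) {
    # isolated internal basic: monobasic, not a site, still recoverable
    pos <- sample(2:(nchar(core) - 1L), 1L)
    basic <- sample(c("K", "R"), 1L)
    left <- substr(core, 1L, pos - 1L)
    right <- substr(core, pos, nchar(core))
    # avoid accidentally forming a site at the insertion point
    if (grepl("[KRG]$", left) || grepl("^[KR]", right)) basic <- ""
    core <- paste0(left, basic, right)
    if (runif(1) < 0.25) {
      # embedded dibasic: a true internal site; planted boundary is lost
      pos <- sample(2:(nchar(core) - 1L), 1L)
      core <- paste0(substr(core, 1L, pos - 1L), "KK",
                     substr(core, pos, nchar(core)))
      core <- sub("G(K|R)", "A\\1", core)  # keep amidation truth clean
      recoverable <- FALSE
    }
  }
  spacer <- function() {
    len <- sample(seq.int(spec$spacer_len_range[1], spec$spacer_len_range[2]), 1L)
    if (len == 0L) "" else random_string(len, SPACER_ALPHABET)
  }
  # GK/GR motifs carry their own donor glycine; planting another would
  # shift the mature boundary by one
  donor <- if (spec$amidated && !startsWith(spec$cleavage_motif, "G"))
    "G" else ""
  chunks <- if (spec$signal) SYNTH_SIGNAL else ""
  cursor <- nchar(chunks)
  truth <- NULL
  for (k in seq_len(spec$n_copies)) {
    sp <- spacer()
    entry <- spec$cleavage_motif
    chunks <- paste0(chunks, sp, entry)
    cursor <- cursor + nchar(sp) + nchar(entry)
    start <- cursor + 1L
    chunks <- paste0(chunks, core, donor, spec$cleavage_motif)
    truth <- rbind(truth, data.frame(
      id = id, start = start, end = cursor + nchar(core),
      mature = core, amidated = spec$amidated,
      recoverable = recoverable, stringsAsFactors = FALSE))
    cursor <- cursor + nchar(core) + nchar(donor) + nchar(spec$cleavage_motif)
  }
  chunks <- paste0(chunks, spacer())
  record <- data.frame(id = id, description = "synthetic precursor",
                       residues = chunks, stringsAsFactors = FALSE)
  list(record = record, truth = truth)
}

#' Generate decoy proteins
#'
#' Three decoy classes: `random` (residues with combined K/R frequency
#' suppressed to 1%, so chance cleavage architecture is rare), `tm`
#' (signal-bearing random protein with a 21-residue internal hydrophobic
#' segment and a matching TM-caller evidence row) and `domainlike`
#' (signal-bearing random protein with a domain-scanner evidence row).
#' TM and domain decoys carry a planted signal peptide so the prefilter
#' drop reason is unambiguously `tm` / `domain`.
#'
#' @param kind `"random"`, `"tm"` or `"domainlike"`.
#' @param n Number of decoys.
#' @param id_prefix Prefix for generated ids.
#' @param len_range Length range of the random portion.
#' @return A list with `records`, `evidence` (a list of
#'   `neuropep_evidence` objects, possibly empty) and `truth` (data frame
#'   `id`, `class`).
#' @export
make_decoys <- function(kind = c("random", "tm", "domainlike"), n,
                        id_prefix = NULL, len_range = c(80L, 200L)) {
  kind <- match.arg(kind)
  if (is.null(id_prefix)) id_prefix <- paste0("decoy_", kind)
  ids <- sprintf("%s_%03d", id_prefix, seq_len(n))
  # residue frequencies: K and R at 0.5% each, the rest uniform
  others <- setdiff(AA_STANDARD, c("K", "R"))
  probs <- c(rep(0.99 / length(others), length(others)), 0.005, 0.005)
  alphabet <- c(others, "K", "R")
  tm_segment <- "ILVFILVFILVFILVFILVFI"  # 21 hydrophobic residues
  seqs <- character(n)
  regions <- NULL
  for (i in seq_len(n)) {
    len <- sample(seq.int(len_range[1], len_range[2]), 1L)
    body <- paste(sample(alphabet, len, TRUE, prob = probs), collapse = "")
    if (kind == "random") {
      seqs[i] <- body
    } else if (kind == "tm") {
      at <- 20L  # insert after 20 residues of mature region
      seqs[i] <- paste0(SYNTH_SIGNAL, substr(body, 1L, at), tm_segment,
                        substr(body, at + 1L, len))
      tm_start <- nchar(SYNTH_SIGNAL) + at + 1L
      regions <- rbind(regions, data.frame(
        id = ids[i], start = tm_start,
        end = tm_start + nchar(tm_segment) - 1L, stringsAsFactors = FALSE))
    } else {
      seqs[i] <- paste0(SYNTH_SIGNAL, body)
    }
  }
  records <- data.frame(id = ids, description = paste("synthetic decoy", kind),
                        residues = seqs, stringsAsFactors = FALSE)
  evidence <- list()
  if (kind == "tm") {
    evidence <- list(structure(list(
      source = "tm_caller",
      table = data.frame(id = ids, n_tm_regions = 1L, stringsAsFactors = FALSE),
      regions = regions), class = "neuropep_evidence"))
  } else if (kind == "domainlike") {
    evidence <- list(structure(list(
      source = "domain_scanner",
      table = data.frame(id = ids, has_domain = TRUE, n_domains = 1L,
                         accession = "PF00089", stringsAsFactors = FALSE),
      regions = NULL), class = "neuropep_evidence"))
  }
  list(records = records,
       evidence = evidence,
       truth = data.frame(id = ids, class = paste0("decoy_", kind),
                          stringsAsFactors = FALSE))
}

#' Generate a gene-by-cluster expression summary from truth classes
#'
#' Neuronal genes draw Poisson counts with mean 5 in two neuronal
#' clusters and mean 0.1 elsewhere; non-neuronal genes are the mirror
#' image (mean 5 in two non-neuronal clusters); ubiquitous genes draw
#' mean 3 everywhere.
#'
#' @param ids Gene ids.
#' @param classes Character vector (`neuronal`, `non_neuronal`,
#'   `ubiquitous`), recycled against `ids`.
#' @param n_neuronal_clusters,n_other_clusters Cluster counts.
#' @param lambda_high,lambda_low,lambda_ubiquitous Poisson means.
#' @return A `neuropep_expression` object.
#' @export
make_expression <- function(ids, classes,
                            n_neuronal_clusters = 3L, n_other_clusters = 4L,
                            lambda_high = 5, lambda_low = 0.1,
                            lambda_ubiquitous = 3) {
  classes <- rep_len(classes, length(ids))
  neuronal <- sprintf("neuron_%d", seq_len(n_neuronal_clusters))
  other <- sprintf("tissue_%d", seq_len(n_other_clusters))
  clusters <- c(neuronal, other)
  mat <- matrix(0, nrow = length(ids), ncol = length(clusters),
                dimnames = list(ids, clusters))
  for (i in seq_along(ids)) {
    lam <- rep(lambda_low, length(clusters))
    if (classes[i] == "neuronal") {
      on <- sample(seq_len(n_neuronal_clusters), min(2L, n_neuronal_clusters))
      lam[on] <- lambda_high
    } else if (classes[i] == "non_neuronal") {
      on <- n_neuronal_clusters +
        sample(seq_len(n_other_clusters), min(2L, n_other_clusters))
      lam[on] <- lambda_high
    } else if (classes[i] == "ubiquitous") {
      lam[] <- lambda_ubiquitous
    } else {
      np_spec_error(sprintf("unknown expression class '%s'", classes[i]))
    }
    mat[i, ] <- rpois(length(clusters), lam)
  }
  structure(list(means = mat, neuronal = neuronal),
            class = "neuropep_expression")
}

# Family templates the benchmark samples cores from. FRamide is omitted:
# its terminal R would merge with the planted site run.
benchmark_core <- function() {
  fam <- sample(c("RFamide", "GLWamide", "PRXamide", "LW_peptide",
                  "KVamide", "unassigned"), 1L)
  prefix <- random_string(sample(3:8, 1L), SPACER_ALPHABET)
  switch(fam,
    RFamide    = list(core = paste0("Q", prefix, "RF"), amidated = TRUE),
    GLWamide   = list(core = paste0(prefix, "GLW"), amidated = TRUE),
    PRXamide   = list(core = paste0("Q", prefix, "PRA"), amidated = TRUE),
    LW_peptide = list(core = paste0(prefix, "LW"), amidated = FALSE),
    KVamide    = list(core = paste0(prefix, "KV"), amidated = TRUE),
    unassigned = list(core = paste0(prefix,
                                    random_string(3L, SPACER_ALPHABET)),
                      amidated = sample(c(TRUE, FALSE), 1L)))
}

#' Generate a full benchmark proteome with ground truth
#'
#' Builds `n_precursors` synthetic precursors (2-4 peptide copies each,
#' cores sampled from the family templates) and `n_decoys` decoys split
#' evenly across the three decoy classes, together with TM/domain
#' evidence, an alignment-hit table (half the precursors get a
#' neuropeptide-precursor-described hit, half the decoys a damning
#' non-neuropeptide hit) and a gene-by-cluster expression summary
#' (precursors neuronal; decoys non-neuronal).
#'
#' @param n_precursors,n_decoys Counts (decoys split across classes).
#' @param adversarial_frac Fraction of precursors given adversarial
#'   cores (see [make_precursor()]).
#' @param seed Optional integer; when given, generation is fully
#'   deterministic and the global RNG state is restored afterwards.
#' @return A list with `records`, `evidence` (list of
#'   `neuropep_evidence`), `expression`, `truth` (protein classes and
#'   expression classes) and `peptide_truth` (planted peptides).
#' @export
make_benchmark <- function(n_precursors = 200L, n_decoys = 600L,
                           adversarial_frac = 0, seed = NULL) {
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    })
    set.seed(seed)
  }
  pre_records <- vector("list", n_precursors)
  pep_truth <- vector("list", n_precursors)
  n_adversarial <- as.integer(round(adversarial_frac * n_precursors))
  adversarial <- c(rep(TRUE, n_adversarial),
                   rep(FALSE, n_precursors - n_adversarial))
  for (i in seq_len(n_precursors)) {
    tpl <- benchmark_core()
    motif_pool <- if (tpl$amidated) DEFAULT_CLEAVAGE_MOTIFS else
      c("KK", "RK", "KR", "RR")
    spec <- precursor_spec(n_copies = sample(2:4, 1L),
                           peptide_core = tpl$core,
                           amidated = tpl$amidated,
                           cleavage_motif = sample(motif_pool, 1L))
    gen <- make_precursor(spec, id = sprintf("precursor_%03d", i),
                          adversarial = adversarial[i])
    pre_records[[i]] <- gen$record
    pep_truth[[i]] <- gen$truth
  }
  precursors <- do.call(rbind, pre_records)
  per_kind <- diff(round(seq(0, n_decoys, length.out = 4L)))
  dec <- mapply(make_decoys, c("random", "tm", "domainlike"), per_kind,
                SIMPLIFY = FALSE)
  records <- rbind(precursors,
                   dec[[1]]$records, dec[[2]]$records, dec[[3]]$records)
  evidence <- c(dec[[1]]$evidence, dec[[2]]$evidence, dec[[3]]$evidence)

  # alignment hits: benign for precursors, damning for half the decoys
  mk_hit <- function(query, desc, identity, evalue, bits) {
    data.frame(query = query, subject = paste0("UR90_", substr(query, 1, 18)),
               pct_identity = identity, length = 60L, mismatches = 10L,
               gapopens = 1L, qstart = 1L, qend = 60L, sstart = 1L,
               send = 60L, e_value = evalue, bitscore = bits,
               description = desc, stringsAsFactors = FALSE)
  }
  hits <- NULL
  pre_with_hit <- precursors$id[runif(n_precursors) < 0.5]
  if (length(pre_with_hit)) {
    hits <- rbind(hits, mk_hit(pre_with_hit,
                               sample(c("FMRFamide neuropeptide precursor",
                                        "prohormone precursor",
                                        "uncharacterized protein"),
                                      length(pre_with_hit), TRUE),
                               runif(length(pre_with_hit), 40, 80),
                               1e-30, 120))
  }
  decoy_ids <- c(dec[[1]]$truth$id, dec[[2]]$truth$id, dec[[3]]$truth$id)
  bad_hit <- decoy_ids[runif(length(decoy_ids)) < 0.5]
  if (length(bad_hit)) {
    hits <- rbind(hits, mk_hit(bad_hit,
                               sample(c("trypsin inhibitor",
                                        "serine protease",
                                        "collagen alpha chain"),
                                      length(bad_hit), TRUE),
                               runif(length(bad_hit), 45, 90), 1e-40, 150))
  }
  evidence <- c(evidence, list(structure(
    list(source = "alignment_hits", table = hits, regions = NULL),
    class = "neuropep_evidence")))

  truth <- data.frame(
    id = records$id,
    class = c(rep("precursor", n_precursors),
              dec[[1]]$truth$class, dec[[2]]$truth$class, dec[[3]]$truth$class),
    expression_class = c(rep("neuronal", n_precursors),
                         rep("non_neuronal", length(decoy_ids))),
    stringsAsFactors = FALSE)
  expression <- make_expression(truth$id, truth$expression_class)
  list(records = records, evidence = evidence, expression = expression,
       truth = truth,
       peptide_truth = do.call(rbind, pep_truth))
}

#' Synthetic stand-ins for the published worked-example precursors
#'
#' Hand-constructed synthetic precursors embodying the reported
#' properties of four published candidate genes (the published precursor
#' sequences themselves are in supplementary material and are not
#' shipped): *Preprohormone E* encodes two amidated RF-terminal peptides;
#' *PRGamide precursor B* encodes two PRX-terminal amidated peptides;
#' *Preprohormone D* encodes two distinct peptides; *LW-peptide precursor
#' A* encodes three copies of the non-amidated LW peptide LWa1
#' (EPEPPETGLW, the published sequence).
#'
#' @return A list with `records` (four-row precursor table) and
#'   `expected` (data frame of the per-precursor expectations used by the
#'   test-suite: counting peptides, families, amidation).
#' @export
worked_example_precursors <- function() {
  sp <- SYNTH_SIGNAL
  assemble <- function(id, peptides, donors, motif = "KR") {
    body <- sp
    for (k in seq_along(peptides)) {
      # the first spacer is short so that, with the heuristic signal end
      # at 14, the leading segment stays below the scanner's min_len and
      # the counting peptides are exactly the planted ones
      body <- paste0(body, if (k == 1L) "S" else "NS", motif, peptides[k],
                     if (donors[k]) "G" else "", motif)
    }
    paste0(body, "ST")
  }
  records <- data.frame(
    id = c("PreprohormoneE_synthetic", "PRGamidePrecursorB_synthetic",
           "PreprohormoneD_synthetic", "LWpeptideA_synthetic"),
    description = c(
      "synthetic stand-in: two amidated RFamide copies",
      "synthetic stand-in: two amidated PRXamide peptides",
      "synthetic stand-in: two distinct amidated peptides",
      "synthetic stand-in: three non-amidated LW peptides (LWa1 core)"),
    residues = c(
      assemble("E", c("QWLSARF", "QSFHLRF"), c(TRUE, TRUE)),
      assemble("B", c("QAPGLPRG", "QNSFLPRG"), c(TRUE, TRUE)),
      assemble("D", c("QNFHLRF", "QWFNSRF"), c(TRUE, TRUE)),
      assemble("A", rep("EPEPPETGLW", 3L), rep(FALSE, 3L))),
    stringsAsFactors = FALSE)
  expected <- data.frame(
    id = records$id,
    n_counting = c(2L, 2L, 2L, 3L),
    family = c("RFamide", "PRXamide", "RFamide", "LW_peptide"),
    amidated = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  list(records = records, expected = expected)
}
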
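# Sequence-similarity classification in the CLANS style: all-versus-all
# local alignment, an e-value graph thresholded at e_cutoff, connected
# components as clusters, and a seeded force-directed 2D layout.
# The external all-vs-all search is replaced by exact Smith-Waterman
# local alignment with ungapped Karlin-Altschul e-values (fixed constants,
# a documented approximation); only determinism and cluster separation
# are contractual for the layout, not specific coordinates.

#' Similarity-clustering configuration
#'
#' @param substitution_matrix Name of a substitution matrix shipped with
#'   Biostrings (default `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap penalties (positive costs;
#'   defaults 11 and 1).
#' @param e_cutoff Edge inclusion threshold on the e-value (default 1e-4).
#' @param K,lambda Ungapped Karlin-Altschul constants used for the
#'   e-value `K * m * n * exp(-lambda * score)` (defaults 0.041 and
#'   0.267 — the standard ungapped BLOSUM62 values, applied here to
#'   gapped scores as a documented approximation).
#' @param layout List of force-layout parameters: `iterations`,
#'   `attraction`, `repulsion`, `damping`, `min_dist`, `seed`.
#' @return A list of class `neuropep_cluster_config`.
#' @export
cluster_config <- function(substitution_matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1,
                           e_cutoff = 1e-4, K = 0.041, lambda = 0.267,
                           layout = list()) {
  if (gap_open <= 0 || gap_extend <= 0) np_usage_error("gap penalties must be > 0")
  if (e_cutoff <= 0) np_usage_error("e_cutoff must be > 0")
  lay <- utils::modifyList(
    list(iterations = 1000L, attraction = 1.0, repulsion = 1.0,
         damping = 0.9, min_dist = 1e-6, seed = 1L, step = 0.01,
         max_step = 0.1),
    layout)
  if (lay$iterations < 1L) np_usage_error("layout iterations must be >= 1")
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = gap_open, gap_extend = gap_extend,
                 e_cutoff = e_cutoff, K = K, lambda = lambda,
                 layout = lay),
            class = "neuropep_cluster_config")
}

get_substitution_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Optimal local alignment score of two sequences
#'
#' Smith-Waterman score under the configured substitution matrix and
#' affine gap penalties, floored at 0 (the empty local alignment).
#' Symmetric in its arguments.
#'
#' @param a,b Residue strings.
#' @param config A [cluster_config()].
#' @return Numeric scalar score.
#' @export
pairwise_local_score <- function(a, b, config = cluster_config()) {
  mat <- get_substitution_matrix(config$substitution_matrix)
  s <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                     substitutionMatrix = mat,
                                     gapOpening = config$gap_open,
                                     gapExtension = config$gap_extend,
                                     scoreOnly = TRUE)
  max(0, s)
}

#' E-value from a local alignment score
#'
#' Karlin-Altschul form `e = K * m * n * exp(-lambda * score)` for
#' sequence lengths `m`, `n`.
#'
#' @param raw_score Non-negative alignment score.
#' @param m,n Lengths of the two sequences.
#' @param config A [cluster_config()].
#' @return Numeric e-value.
#' @export
evalue_from_score <- function(raw_score, m, n, config = cluster_config()) {
  config$K * m * n * exp(-config$lambda * raw_score)
}

#' Build an all-versus-all similarity graph
#'
#' Evaluates every unordered pair of sequences once and keeps edges whose
#' e-value is at most `e_cutoff`. Nodes are stored sorted by id so that
#' downstream cluster labels are invariant under input order.
#'
#' @param sequences Named character vector of residue strings (names are
#'   node ids), or a precursor table with `id` and `residues` columns.
#' @param config A [cluster_config()].
#' @return An object of class `neuropep_simgraph`: list with `nodes`
#'   (sorted ids), `lengths`, and `edges` (data frame `i`, `j`,
#'   `raw_score`, `e_value`, sorted by `(i, j)`; `i < j` in id order).
#' @export
build_graph <- function(sequences, config = cluster_config()) {
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$residues, sequences$id)
  }
  if (length(sequences) < 2L) {
    np_usage_error("similarity clustering needs at least 2 sequences")
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    np_usage_error("sequences must have unique names")
  }
  sequences <- sequences[order(names(sequences))]
  ids <- names(sequences)
  n <- length(sequences)
  mat <- get_substitution_matrix(config$substitution_matrix)
  lens <- nchar(sequences)
  ii <- integer(0); jj <- integer(0); sc <- numeric(0)
  for (j in 2:n) {
    s <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(sequences[seq_len(j - 1L)]), sequences[[j]],
      type = "local", substitutionMatrix = mat,
      gapOpening = config$gap_open, gapExtension = config$gap_extend,
      scoreOnly = TRUE)
    s <- pmax(0, s)
    ii <- c(ii, seq_len(j - 1L)); jj <- c(jj, rep(j, j - 1L))
    sc <- c(sc, s)
  }
  ev <- config$K * lens[ii] * lens[jj] * exp(-config$lambda * sc)
  keep <- ev <= config$e_cutoff
  edges <- data.frame(i = ids[ii[keep]], j = ids[jj[keep]],
                      raw_score = sc[keep], e_value = ev[keep],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$i, edges$j), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = ids, lengths = unname(lens), edges = edges),
            class = "neuropep_simgraph")
}

#' Label connected-component clusters
#'
#' Clusters are the connected components of the thresholded similarity
#' graph. Non-singleton components are labelled `cluster_1`,
#' `cluster_2`, ... ordered by decreasing size, ties broken by smallest
#' member id; single nodes are labelled `singleton`.
#'
#' @param graph A `neuropep_simgraph` from [build_graph()].
#' @return Data frame `id`, `cluster_label`, ordered by id.
#' @export
connected_clusters <- function(graph) {
  stopifnot(inherits(graph, "neuropep_simgraph"))
  g <- igraph::graph_from_data_frame(graph$edges[, c("i", "j")],
                                     directed = FALSE,
                                     vertices = data.frame(name = graph$nodes))
  comp <- igraph::components(g)
  membership <- comp$membership[graph$nodes]
  size <- comp$csize[membership]
  # order components: decreasing size, then smallest member id
  comp_ids <- seq_len(comp$no)
  min_member <- vapply(comp_ids, function(k)
    min(graph$nodes[membership == k]), character(1))
  ord <- order(-comp$csize, min_member)
  rank <- match(comp_ids, comp_ids[ord])
  nonsingleton <- comp$csize >= 2L
  # ranks restricted to non-singleton components, renumbered 1..k
  ns_rank <- match(rank, sort(rank[nonsingleton]))
  label <- ifelse(nonsingleton[membership],
                  sprintf("cluster_%d", ns_rank[membership]), "singleton")
  data.frame(id = graph$nodes, cluster_label = label,
             stringsAsFactors = FALSE)
}

#' Seeded force-directed 2D layout
#'
#' Positions are initialized uniformly at random in the unit square from
#' the configured seed. Each iteration applies, per edge, an attractive
#' force `attraction * w * (pj - pi)` with `w = min(1, -log10(e)/10)`,
#' and, per node pair, a repulsive force of magnitude
#' `repulsion / max(dist, min_dist)` directed apart; positions are
#' updated with velocity damping for exactly `iterations` steps.
#' Deterministic (bit-for-bit) for a fixed seed and graph. The global
#' RNG state is left untouched.
#'
#' @param graph A `neuropep_simgraph`.
#' @param config A [cluster_config()]; the `layout` element holds the
#'   force parameters and seed.
#' @return Data frame `id`, `x`, `y` ordered as `graph$nodes`.
#' @export
force_layout <- function(graph, config = cluster_config()) {
  stopifnot(inherits(graph, "neuropep_simgraph"))
  lay <- config$layout
  n <- length(graph$nodes)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(lay$seed)
  pos <- matrix(runif(2L * n), ncol = 2L)
  vel <- matrix(0, nrow = n, ncol = 2L)
  ei <- match(graph$edges$i, graph$nodes)
  ej <- match(graph$edges$j, graph$nodes)
  w <- pmin(1, -log10(graph$edges$e_value) / 10)
  w <- pmax(w, 0)
  for (iter in seq_len(lay$iterations)) {
    force <- matrix(0, nrow = n, ncol = 2L)
    if (n > 1L) {
      dx <- outer(pos[, 1], pos[, 1], "-")  # dx[i,j] = xi - xj
      dy <- outer(pos[, 2], pos[, 2], "-")
      d <- sqrt(dx^2 + dy^2)
      d <- pmax(d, lay$min_dist)
      diag(d) <- Inf
      mag <- lay$repulsion / d^2  # magnitude/d applied to unit vector
      force[, 1] <- rowSums(mag * dx)
      force[, 2] <- rowSums(mag * dy)
    }
    if (length(ei)) {
      fx <- lay$attraction * w * (pos[ej, 1] - pos[ei, 1])
      fy <- lay$attraction * w * (pos[ej, 2] - pos[ei, 2])
      force[, 1] <- force[, 1] + tapply2(fx, ei, n) - tapply2(fx, ej, n)
      force[, 2] <- force[, 2] + tapply2(fy, ei, n) - tapply2(fy, ej, n)
    }
    vel <- (vel + lay$step * force) * lay$damping
    step_len <- sqrt(rowSums(vel^2))
    too_big <- step_len > lay$max_step
    if (any(too_big)) {
      vel[too_big, ] <- vel[too_big, ] * (lay$max_step / step_len[too_big])
    }
    pos <- pos + vel
  }
  data.frame(id = graph$nodes, x = pos[, 1], y = pos[, 2],
             stringsAsFactors = FALSE)
}

# sum `values` into n bins by integer index (fast deterministic tapply)
tapply2 <- function(values, index, n) {
  out <- numeric(n)
  acc <- rowsum(values, index)
  out[as.integer(rownames(acc))] <- acc[, 1]
  out
}
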
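#' Binarize a connectivity matrix into an adjacency matrix
#'
#' Edge (i, j) is kept iff its weight is strictly greater than the threshold;
#' the diagonal is forced to zero. The default threshold 0.5 follows the
#' assessment workflow's convention; verdicts are expected to be robust over
#' roughly 0.2--0.8 (see [threshold_sweep()]).
#'
#' @param m a [conn_matrix()].
#' @param threshold finite scalar cut-off.
#' @return An `adjacency` object: `a` (binary symmetric N x N, zero
#'   diagonal), `threshold_used`, `subject_id`.
#' @export
binarize <- function(m, threshold = 0.5) {
  stopifnot(inherits(m, "conn_matrix"))
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold)) {
    abort("`threshold` must be a single finite number.")
  }
  adjacency_from_weights(m$weights, threshold, m$subject_id)
}

# Harmonized weights can step outside [-1, 1]; thresholding is tolerant, so
# adjacency construction accepts any symmetric weight matrix.
adjacency_from_weights <- function(w, threshold, subject_id) {
  a <- (w > threshold) * 1L
  diag(a) <- 0L
  structure(list(a = a, threshold_used = threshold, subject_id = subject_id),
            class = "adjacency")
}

#' @export
print.adjacency <- function(x, ...) {
  cat(sprintf("<adjacency> %s: %d nodes, %d edges (threshold %g)\n",
              x$subject_id, nrow(x$a), sum(x$a) / 2, x$threshold_used))
  invisible(x)
}

#' Single-step random-walk distribution from one node
#'
#' The probability that a random walk leaves node i toward node j is 1/k_i if
#' the edge exists and 0 otherwise, where k_i is the degree of i. Entries are
#' returned in ascending node order, skipping j = i (length N - 1). Isolated
#' nodes (k_i = 0) get an all-zero vector and are flagged.
#'
#' @param a an `adjacency` from [binarize()].
#' @param i node index in 1..N.
#' @return A list with `node`, `probs`, `degree`, `isolated`.
#' @export
walk_distribution <- function(a, i) {
  stopifnot(inherits(a, "adjacency"))
  n <- nrow(a$a)
  if (!(i >= 1L && i <= n && i == round(i))) {
    abort(sprintf("Node index %s out of 1..%d.", format(i), n))
  }
  row <- a$a[i, -i]
  k <- sum(row)
  probs <- if (k > 0) row / k else row * 0
  list(node = as.integer(i), probs = as.numeric(probs),
       degree = as.integer(k), isolated = k == 0L)
}

#' Normalized nodal Shannon entropy
#'
#' S of the node's walk distribution (natural log, with 0 ln 0 = 0), scaled
#' by ln(N - 1) so a node connected to every other node scores 1. Isolated
#' nodes score 0 by the ordered-state convention.
#'
#' @param d a node distribution from [walk_distribution()].
#' @param n total node count N (>= 3; ln(N - 1) is degenerate at N = 2).
#' @return A number in \[0, 1\].
#' @export
nodal_entropy <- function(d, n) {
  if (n < 3L) abort("Nodal entropy requires N >= 3.")
  if (d$isolated) return(0)
  p <- d$probs[d$probs > 0]
  s <- -sum(p * log(p))
  s / log(n - 1)
}

#' Normalized nodal Fisher information
#'
#' One half the summed squared jumps of sqrt(p) between consecutive entries
#' of the node's walk distribution (taken in ascending node order). A node
#' whose neighbors are spread uniformly over all others scores 0; isolated
#' nodes score 1 by the ordered-state convention.
#'
#' @param d a node distribution from [walk_distribution()].
#' @return A number in \[0, 1\].
#' @export
nodal_fisher <- function(d) {
  if (d$isolated) return(1)
  sp <- sqrt(d$probs)
  0.5 * sum(diff(sp)^2)
}

#' Normalized network Shannon entropy (SE)
#'
#' Mean of [nodal_entropy()] over all nodes: tends to 0 for sparse networks
#' and equals 1 for a complete graph.
#'
#' @param a an `adjacency`.
#' @return A number in \[0, 1\].
#' @export
network_entropy <- function(a) {
  stopifnot(inherits(a, "adjacency"))
  n <- nrow(a$a)
  mean(vapply(seq_len(n), function(i) nodal_entropy(walk_distribution(a, i), n),
              numeric(1)))
}

#' Normalized network Fisher information (FI)
#'
#' Mean of [nodal_fisher()] over all nodes: 0 for a complete graph, 1 for an
#' empty one.
#'
#' @param a an `adjacency`.
#' @return A number in \[0, 1\].
#' @export
network_fisher <- function(a) {
  stopifnot(inherits(a, "adjacency"))
  n <- nrow(a$a)
  mean(vapply(seq_len(n), function(i) nodal_fisher(walk_distribution(a, i)),
              numeric(1)))
}

#' Place one connectome on the Shannon-Fisher plane
#'
#' Binarizes the matrix and computes (H, F). On the plane, very ordered
#' (sparse) networks sit near (0, 1) and very disordered (dense) networks
#' near (1, 0).
#'
#' @param m a [conn_matrix()].
#' @param threshold binarization threshold.
#' @param site site label to attach (optional).
#' @return A one-row tibble: `subject_id`, `site`, `H`, `F`.
#' @export
shannon_fisher_point <- function(m, threshold = 0.5, site = NA_character_) {
  a <- binarize(m, threshold)
  tibble::tibble(subject_id = m$subject_id, site = as.character(site),
                 H = network_entropy(a), F = network_fisher(a))
}

#' Shannon-Fisher plane points for a whole cohort
#'
#' Rebuilds each subject's connectivity matrix from the cohort feature table,
#' binarizes at `threshold`, and returns the (H, F) coordinates with site
#' labels — the input to [assess_cohort()] and [plot_plane()].
#'
#' @param cohort a `conn_cohort`.
#' @param threshold binarization threshold (default 0.5).
#' @return A tibble with one row per subject: `subject_id`, `site`, `H`,
#'   `F`.
#' @export
shannon_fisher_points <- function(cohort, threshold = 0.5) {
  stopifnot(inherits(cohort, "conn_cohort"))
  n <- cohort$n_rois
  pts <- purrr::map2_dfr(
    seq_len(nrow(cohort$features)), cohort$phenotypes$site,
    function(i, site) {
      w <- weights_from_features(cohort$features[i, ], n)
      a <- adjacency_from_weights(w, threshold,
                                  cohort$phenotypes$subject_id[i])
      tibble::tibble(subject_id = a$subject_id, site = as.character(site),
                     H = network_entropy(a), F = network_fisher(a))
    })
  class(pts) <- c("sf_plane", class(pts))
  pts
}
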
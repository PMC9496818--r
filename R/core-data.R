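#' Construct a subject time-series object
#'
#' Container for one subject's ROI-by-timepoint BOLD signals together with the
#' sampling metadata the connectivity stage needs.
#'
#' @param values numeric matrix, timepoints (rows) by ROIs (columns).
#' @param subject_id character scalar identifying the subject.
#' @param tr repetition time in seconds (time between consecutive rows).
#' @return An object of class `subject_ts` with fields `subject_id`, `values`
#'   (T x N matrix) and `tr`.
#' @examples
#' ts <- subject_ts(matrix(rnorm(300), 100, 3), "sub-01", tr = 2)
#' dim(ts$values)
#' @export
subject_ts <- function(values, subject_id, tr) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.character(subject_id) || length(subject_id) != 1L || is.na(subject_id)) {
    abort("`subject_id` must be a single non-missing string.")
  }
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0) {
    abort("`tr` must be a single positive number (seconds per sample).")
  }
  if (nrow(values) < 3L) {
    abort(sprintf("Time series for '%s' has %d timepoints; at least 3 required.",
                  subject_id, nrow(values)))
  }
  if (ncol(values) < 3L) {
    abort(sprintf("Time series for '%s' has %d ROIs; at least 3 required.",
                  subject_id, ncol(values)))
  }
  if (anyNA(values) || any(!is.finite(values))) {
    abort(sprintf("Time series for '%s' contains missing or non-finite values.",
                  subject_id))
  }
  structure(list(subject_id = subject_id, values = values, tr = tr),
            class = "subject_ts")
}

#' @export
print.subject_ts <- function(x, ...) {
  cat(sprintf("<subject_ts> %s: %d timepoints x %d ROIs, tr = %g s\n",
              x$subject_id, nrow(x$values), ncol(x$values), x$tr))
  invisible(x)
}

# Delimiter sniffing: pick the candidate that splits the first data line into
# the most fields, consistently across the first few lines.
sniff_delim <- function(lines) {
  cands <- c(comma = ",", tab = "\t", whitespace = "")
  counts <- vapply(cands, function(s) {
    if (s == "") length(strsplit(trimws(lines[1]), "[ \t]+")[[1]])
    else length(strsplit(lines[1], s, fixed = TRUE)[[1]])
  }, integer(1))
  cands[[which.max(counts)]]
}

#' Read one subject's ROI time series from a delimited text file
#'
#' Reads a plain-text numeric table (timepoints by ROIs). The delimiter is
#' sniffed among comma, tab and whitespace; a header row is auto-detected
#' (first row non-numeric) and stripped.
#'
#' @param path path to a CSV/TSV/whitespace-delimited numeric matrix.
#' @param subject_id subject identifier to attach.
#' @param tr repetition time in seconds.
#' @return A [subject_ts()] object.
#' @export
read_time_series <- function(path, subject_id, tr) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(sprintf("File is empty: %s", path))
  sep <- sniff_delim(lines)
  first <- scan(text = lines[1], what = "character",
                sep = if (sep == "") "" else sep, quiet = TRUE, strip.white = TRUE)
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  df <- tryCatch(
    read.table(text = paste(lines, collapse = "\n"), sep = sep,
               header = has_header, colClasses = "character",
               strip.white = TRUE),
    error = function(e) abort(sprintf("Failed to parse '%s': %s", path,
                                      conditionMessage(e))))
  m <- as.matrix(df)
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
  bad <- which(is.na(num) | !is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf(
      "Non-numeric or missing cell in '%s' at data row %d, column %d (value '%s').",
      path, bad[1, 1], bad[1, 2], m[bad[1, 1], bad[1, 2]]))
  }
  dimnames(num) <- NULL
  subject_ts(num, subject_id = subject_id, tr = tr)
}

#' Read a phenotype table
#'
#' Reads the cohort phenotype CSV. Columns `subject_id` and `site` are
#' mandatory; `age`, `sex`, `diagnosis` and `tr` are optional — covariates
#' that are absent are simply unavailable to the harmonization design matrix
#' (a warning is emitted naming them).
#'
#' @param path path to a CSV file with a header row.
#' @return A tibble with `subject_id` and `site` as character columns plus any
#'   optional columns present.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  phen <- tibble::as_tibble(df)
  validate_phenotypes(phen)
}

validate_phenotypes <- function(phen, require_min_site = TRUE) {
  phen <- tibble::as_tibble(phen)
  need <- setdiff(c("subject_id", "site"), names(phen))
  if (length(need) > 0L) {
    abort(sprintf("Phenotype table is missing mandatory column(s): %s",
                  paste(need, collapse = ", ")))
  }
  phen$subject_id <- as.character(phen$subject_id)
  phen$site <- as.character(phen$site)
  if (anyDuplicated(phen$subject_id)) {
    dups <- unique(phen$subject_id[duplicated(phen$subject_id)])
    abort(sprintf("Duplicated subject_id(s): %s", paste(dups, collapse = ", ")))
  }
  opt <- setdiff(c("age", "sex", "diagnosis", "tr"), names(phen))
  if (length(opt) > 0L) {
    warn(sprintf("Optional phenotype column(s) absent: %s; they cannot be used as covariates.",
                 paste(opt, collapse = ", ")))
  }
  for (cv in intersect(c("age", "sex", "diagnosis"), names(phen))) {
    if (anyNA(phen[[cv]])) {
      abort(sprintf("Covariate column '%s' has missing entries; design matrices require complete covariates.", cv))
    }
  }
  phen
}

#' Construct a connectivity matrix object
#'
#' @param weights symmetric N x N numeric matrix with unit diagonal.
#' @param subject_id subject identifier.
#' @param kind `"phase_interaction"` or `"pearson"`.
#' @param tol symmetry tolerance.
#' @return An object of class `conn_matrix`.
#' @export
conn_matrix <- function(weights, subject_id,
                        kind = c("phase_interaction", "pearson"),
                        tol = 1e-10) {
  kind <- match.arg(kind)
  weights <- as.matrix(weights)
  n <- nrow(weights)
  if (n < 3L || ncol(weights) != n) {
    abort("`weights` must be a square matrix with N >= 3.")
  }
  if (max(abs(weights - t(weights))) > tol) {
    abort(sprintf("Connectivity matrix for '%s' is asymmetric beyond tolerance %g.",
                  subject_id, tol))
  }
  weights <- (weights + t(weights)) / 2
  if (max(abs(diag(weights) - 1)) > 1e-8) {
    abort(sprintf("Connectivity matrix for '%s' must have unit diagonal.", subject_id))
  }
  diag(weights) <- 1
  if (kind == "phase_interaction" &&
      (min(weights) < -1 - 1e-8 || max(weights) > 1 + 1e-8)) {
    abort("Phase-interaction entries must lie in [-1, 1].")
  }
  structure(list(subject_id = subject_id, weights = weights, kind = kind,
                 n_rois = n),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> %s: %d x %d (%s)\n",
              x$subject_id, x$n_rois, x$n_rois, x$kind))
  invisible(x)
}

#' Vectorize a connectivity matrix into its edge features
#'
#' Extracts the strict upper triangle in row-major order (edge (1,2), (1,3),
#' ..., (1,N), (2,3), ...), the per-subject feature layout harmonization
#' operates on. The diagonal (self-coherence, identically 1) is excluded.
#'
#' @param m a [conn_matrix()] object.
#' @return A list of class `edge_vector` with `subject_id`, `features`
#'   (length N(N-1)/2 numeric) and `n_rois`.
#' @seealso [devectorize()] for the lossless inverse.
#' @export
vectorize_matrix <- function(m) {
  stopifnot(inherits(m, "conn_matrix"))
  w <- m$weights
  # t(w)[lower.tri] walks the upper triangle row-major
  feats <- t(w)[lower.tri(w)]
  structure(list(subject_id = m$subject_id, features = feats,
                 n_rois = m$n_rois, kind = m$kind),
            class = "edge_vector")
}

#' Rebuild a connectivity matrix from its edge-feature vector
#'
#' Inverse of [vectorize_matrix()]: fills the strict upper triangle row-major,
#' mirrors it, and restores the unit diagonal.
#'
#' @param v an `edge_vector`, or a bare numeric vector (then `n_rois`,
#'   `subject_id` and `kind` must be supplied).
#' @param n_rois,subject_id,kind used when `v` is a bare numeric vector.
#' @return A [conn_matrix()] object.
#' @export
devectorize <- function(v, n_rois = NULL, subject_id = "subject",
                        kind = "phase_interaction") {
  if (inherits(v, "edge_vector")) {
    n_rois <- v$n_rois
    subject_id <- v$subject_id
    kind <- v$kind %||% kind
    v <- v$features
  }
  if (is.null(n_rois)) abort("`n_rois` is required for a bare feature vector.")
  expected <- n_rois * (n_rois - 1L) / 2L
  if (length(v) != expected) {
    abort(sprintf("Feature vector has length %d; N = %d requires N(N-1)/2 = %d.",
                  length(v), n_rois, expected))
  }
  conn_matrix(weights_from_features(v, n_rois), subject_id = subject_id,
              kind = kind)
}

# strict upper triangle, row-major -> full symmetric matrix, unit diagonal
weights_from_features <- function(v, n_rois) {
  w <- matrix(0, n_rois, n_rois)
  w[lower.tri(w)] <- v     # column-major lower triangle == row-major upper
  w <- t(w)
  w <- w + t(w)
  diag(w) <- 1
  w
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a cohort feature table from per-subject edge vectors
#'
#' Joins edge vectors to the phenotype table by `subject_id` (never by
#' position) and stacks them, in phenotype row order, into the
#' subjects-by-edges matrix that harmonization operates on.
#'
#' @param vectors list of `edge_vector` objects (from [vectorize_matrix()]).
#' @param phen phenotype data frame with at least `subject_id` and `site`.
#' @return A `conn_cohort` object: `features` (J x V matrix, rownames =
#'   subject ids), `phenotypes` (tibble, aligned by row) and `n_rois`.
#' @export
assemble_cohort <- function(vectors, phen) {
  phen <- validate_phenotypes(phen)
  ids <- vapply(vectors, function(v) v$subject_id, character(1))
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicated edge vectors for subject(s): %s",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  nr <- vapply(vectors, function(v) v$n_rois, integer(1))
  if (length(unique(nr)) > 1L) {
    abort(sprintf("Mixed ROI counts among edge vectors: %s",
                  paste(sort(unique(nr)), collapse = ", ")))
  }
  missing <- setdiff(ids, phen$subject_id)
  if (length(missing) > 0L) {
    abort(sprintf("Subject(s) absent from phenotype table: %s",
                  paste(missing, collapse = ", ")))
  }
  phen <- dplyr::filter(phen, .data$subject_id %in% ids)
  feats <- do.call(rbind, lapply(vectors, function(v) v$features))
  rownames(feats) <- ids
  feats <- feats[phen$subject_id, , drop = FALSE]
  new_conn_cohort(feats, phen, n_rois = nr[1])
}

#' Construct a cohort object directly from a feature matrix
#'
#' @param features J x V numeric matrix (subjects by edges); rownames, if
#'   present, must match `phenotypes$subject_id` in order.
#' @param phenotypes phenotype tibble aligned by row.
#' @param n_rois number of ROIs N, with V = N(N-1)/2.
#' @return A `conn_cohort` object.
#' @export
new_conn_cohort <- function(features, phenotypes, n_rois) {
  phenotypes <- validate_phenotypes(phenotypes)
  features <- as.matrix(features)
  if (nrow(features) != nrow(phenotypes)) {
    abort(sprintf("features has %d rows but phenotypes has %d.",
                  nrow(features), nrow(phenotypes)))
  }
  expected <- n_rois * (n_rois - 1L) / 2L
  if (ncol(features) != expected) {
    abort(sprintf("features has %d columns; N = %d requires %d.",
                  ncol(features), n_rois, expected))
  }
  rownames(features) <- phenotypes$subject_id
  structure(list(features = features, phenotypes = phenotypes,
                 n_rois = as.integer(n_rois)),
            class = "conn_cohort")
}

#' @export
print.conn_cohort <- function(x, ...) {
  cat(sprintf("<conn_cohort> %d subjects x %d edge features (N = %d ROIs), %d site(s)\n",
              nrow(x$features), ncol(x$features), x$n_rois,
              length(unique(x$phenotypes$site))))
  invisible(x)
}

#' Per-site subject counts of a cohort
#' @param cohort a `conn_cohort`.
#' @return A tibble with columns `site` and `n`.
#' @export
cohort_sites <- function(cohort) {
  dplyr::count(cohort$phenotypes, .data$site, name = "n")
}

#' Write / read a connectivity matrix as CSV plus a JSON sidecar
#'
#' The matrix is stored as a headerless N x N CSV; `{subject_id, kind,
#' n_rois}` go to `<path>.json`.
#'
#' @param m a [conn_matrix()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_conn_matrix <- function(m, path) {
  stopifnot(inherits(m, "conn_matrix"))
  utils::write.table(m$weights, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(
    list(subject_id = m$subject_id, kind = m$kind, n_rois = m$n_rois),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_conn_matrix
#' @export
read_conn_matrix <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  w <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(w) <- NULL
  conn_matrix(w, subject_id = meta$subject_id, kind = meta$kind, tol = 1e-8)
}
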
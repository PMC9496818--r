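#' Fit the traveling-subject measurement-bias model
#'
#' A traveling-subject design scans the same reference participants at every
#' site, which makes the per-site measurement bias identifiable separately
#' from sampling bias. For each edge feature v the model is
#' \deqn{y_{jv} = x^m_j m_v + x^d_j d_v + x^p_j p_v + const_v + e,}
#' with one-hot site (`m`, measurement bias), diagnosis (`d`, present only if
#' the traveling cohort contains multiple diagnosis levels — reference
#' travelers are healthy, so it normally drops), and participant (`p`,
#' subject factor) terms, fitted by ridge-penalized least squares under
#' sum-to-zero constraints on m, d and p. The measurement bias is estimated
#' from the traveling data only; [apply_traveling_subject()] then subtracts
#' it from any cohort scanned at the same sites.
#'
#' @param traveling a `conn_cohort` in which the same `subject_id` base
#'   identities recur across sites. Row identity is taken from the phenotype
#'   column `traveler_id` if present, otherwise from `subject_id` stripped of
#'   a trailing `"_<site>"` tag.
#' @param lambda_l2 ridge penalty on the m, d and p coefficient blocks
#'   (default 0.1; the constant is never penalized).
#' @return A `traveling_model` with `m_hat` (site x feature measurement
#'   biases, columns summing to zero over sites), `p_hat`, `d_hat`, `const`,
#'   `site_labels`, `lambda_l2`.
#' @export
fit_traveling_subject <- function(traveling, lambda_l2 = 0.1) {
  stopifnot(inherits(traveling, "conn_cohort"))
  if (!is.numeric(lambda_l2) || lambda_l2 < 0) {
    abort("`lambda_l2` must be a non-negative number.")
  }
  phen <- traveling$phenotypes
  traveler <- traveler_ids(phen)
  sites_per <- tapply(phen$site, traveler, function(s) length(unique(s)))
  if (max(sites_per) < 2L) {
    abort("No participant appears at >= 2 sites: not a traveling-subject design.")
  }
  sites <- sort(unique(phen$site))
  people <- sort(unique(traveler))
  y <- traveling$features

  cs <- stats::contr.sum(length(sites))
  cp <- stats::contr.sum(length(people))
  bs <- stats::model.matrix(~ 0 + factor(phen$site, levels = sites)) %*% cs
  bp <- stats::model.matrix(~ 0 + factor(traveler, levels = people)) %*% cp

  diagnoses <- if ("diagnosis" %in% names(phen)) {
    sort(unique(as.character(phen$diagnosis)))
  } else character(0)
  use_d <- length(diagnoses) >= 2L
  if (use_d) {
    cd <- stats::contr.sum(length(diagnoses))
    bd <- stats::model.matrix(
      ~ 0 + factor(as.character(phen$diagnosis), levels = diagnoses)) %*% cd
  } else {
    bd <- matrix(numeric(0), nrow(y), 0)
  }

  x <- cbind(1, bs, bd, bp)
  # ridge on the constrained effects themselves: ||m||^2 = u' (C'C) u etc.
  pen <- matrix(0, ncol(x), ncol(x))
  blocks <- list(s = list(off = 1L, c = cs),
                 d = if (use_d) list(off = 1L + ncol(bs), c = cd),
                 p = list(off = 1L + ncol(bs) + ncol(bd), c = cp))
  for (bl in blocks) {
    if (is.null(bl)) next
    i <- bl$off + seq_len(ncol(bl$c))
    pen[i, i] <- crossprod(bl$c)
  }
  theta <- solve(crossprod(x) + lambda_l2 * pen, crossprod(x, y))

  const <- theta[1L, ]
  u_s <- theta[1L + seq_len(ncol(bs)), , drop = FALSE]
  m_hat <- cs %*% u_s
  rownames(m_hat) <- sites
  d_hat <- if (use_d) {
    dh <- cd %*% theta[1L + ncol(bs) + seq_len(ncol(bd)), , drop = FALSE]
    rownames(dh) <- diagnoses
    dh
  } else NULL
  u_p <- theta[1L + ncol(bs) + ncol(bd) + seq_len(ncol(bp)), , drop = FALSE]
  p_hat <- cp %*% u_p
  rownames(p_hat) <- people

  structure(list(m_hat = m_hat, p_hat = p_hat, d_hat = d_hat,
                 const = const, site_labels = sites, travelers = people,
                 diagnoses = if (use_d) diagnoses else character(0),
                 lambda_l2 = lambda_l2),
            class = "traveling_model")
}

# Traveling rows need an identity that survives being scanned at several
# sites while subject_id stays unique per row.
traveler_ids <- function(phen) {
  if ("traveler_id" %in% names(phen)) return(as.character(phen$traveler_id))
  sub("_[^_]+$", "", phen$subject_id)
}

#' Subtract estimated measurement biases from a cohort
#'
#' \eqn{y^{Traveling}_{jv} = y_{jv} - x^m_j \hat m_v}: each subject's features
#' lose the measurement bias of the site they were scanned at; nothing else
#' changes. Applying the model twice subtracts the bias twice (the operation
#' is a fixed translation per site, not a projection).
#'
#' @param model a `traveling_model` from [fit_traveling_subject()].
#' @param cohort a `conn_cohort` whose sites all have an estimated bias.
#' @return The harmonized `conn_cohort`.
#' @export
apply_traveling_subject <- function(model, cohort) {
  stopifnot(inherits(model, "traveling_model"), inherits(cohort, "conn_cohort"))
  unseen <- setdiff(unique(cohort$phenotypes$site), model$site_labels)
  if (length(unseen) > 0L) {
    abort(sprintf("Site(s) without an estimated measurement bias: %s",
                  paste(unseen, collapse = ", ")))
  }
  idx <- match(cohort$phenotypes$site, model$site_labels)
  out <- cohort
  out$features <- cohort$features - model$m_hat[idx, , drop = FALSE]
  rownames(out$features) <- rownames(cohort$features)
  out
}

#' @export
print.traveling_model <- function(x, ...) {
  cat(sprintf(
    "<traveling_model> %d sites x %d features, %d travelers; lambda = %g\n",
    length(x$site_labels), ncol(x$m_hat), length(x$travelers), x$lambda_l2))
  invisible(x)
}

#' Tidy a fitted traveling-subject model
#'
#' @param x a `traveling_model`.
#' @param ... unused.
#' @return A tibble with one row per site/feature: `site`, `feature`,
#'   `m_hat`.
#' @method tidy traveling_model
#' @export
tidy.traveling_model <- function(x, ...) {
  s <- length(x$site_labels); v <- ncol(x$m_hat)
  tibble::tibble(
    site = rep(x$site_labels, each = v),
    feature = rep(seq_len(v), times = s),
    m_hat = as.numeric(t(x$m_hat)))
}

#' @rdname tidy.traveling_model
#' @method glance traveling_model
#' @export
glance.traveling_model <- function(x, ...) {
  tibble::tibble(
    n_sites = length(x$site_labels),
    n_features = ncol(x$m_hat),
    n_travelers = length(x$travelers),
    lambda_l2 = x$lambda_l2,
    m_rms = sqrt(mean(x$m_hat^2)))
}
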
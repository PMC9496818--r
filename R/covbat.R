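#' CovBat: correct covariance site effects on top of ComBat
#'
#' ComBat aligns per-feature means and variances across sites but leaves
#' within-site covariance untouched. CovBat additionally models the
#' ComBat-adjusted residuals in their principal-component basis: the score of
#' component k for a subject at site t is taken as
#' \eqn{\xi_{tjk} = \mu_{tk} + \rho_{tk}\,\epsilon_{tjk}}, and each site's
#' score center \eqn{\hat\mu_{tk}} and scale \eqn{\hat\rho_{tk}} (relative to
#' the pooled score scale) are removed for the leading K components:
#' \eqn{\xi^{CovBat}_{tjk} = (\xi_{tjk} - \hat\mu_{tk}) / \hat\rho_{tk}}.
#' Residuals are rebuilt from the corrected leading scores plus the raw
#' trailing scores, and the intercept and protected covariate effects are
#' added back.
#'
#' @inheritParams fit_combat
#' @param var_frac fraction of residual variance the corrected components
#'   must capture; K is the smallest count reaching it. Default 0.9.
#' @return A list with elements `cohort` (the harmonized `conn_cohort`) and
#'   `model` (a `covbat_model` wrapping the underlying `combat_model`, the
#'   principal axes, and the per-site score parameters).
#' @export
covbat <- function(cohort, covariates = NULL, var_frac = 0.9, ...) {
  stopifnot(inherits(cohort, "conn_cohort"))
  if (!is.numeric(var_frac) || length(var_frac) != 1L ||
      var_frac <= 0 || var_frac > 1) {
    abort("`var_frac` must lie in (0, 1].")
  }
  if (nrow(cohort$features) < 3L) {
    abort("CovBat requires at least 3 subjects.")
  }
  cb <- fit_combat(cohort, covariates = covariates, ...)
  combat_cohort <- apply_combat(cb, cohort)

  phen <- cohort$phenotypes
  cmat <- build_covariate_matrix(phen, cb$design_spec)
  j <- nrow(combat_cohort$features)
  stand_mean <- outer(rep(1, j), cb$alpha)
  if (ncol(cmat) > 0L) stand_mean <- stand_mean + cmat %*% cb$beta
  resid <- combat_cohort$features - stand_mean

  pc <- prcomp(resid, center = TRUE, scale. = FALSE)
  eigvals <- pc$sdev^2
  pos <- eigvals > max(eigvals) * 1e-12
  cumfrac <- cumsum(eigvals) / sum(eigvals)
  k <- which(cumfrac >= var_frac - 1e-12)[1]
  k <- min(k, sum(pos))
  scores <- pc$x

  sites <- cb$site_labels
  idx <- match(phen$site, sites)
  lead <- scores[, seq_len(k), drop = FALSE]
  mu_site <- rowsum(lead, phen$site)[sites, , drop = FALSE] /
    cb$n_per_site
  sd_site <- t(vapply(sites, function(s) {
    apply(lead[phen$site == s, , drop = FALSE], 2L, sd)
  }, numeric(k)))
  sd_pooled <- apply(lead, 2L, sd)
  rho_site <- sweep(sd_site, 2L, sd_pooled, "/")
  if (any(!is.finite(rho_site)) || any(rho_site <= 0)) {
    abort("Degenerate score scale at some site (zero within-site score variance).")
  }
  rownames(mu_site) <- rownames(rho_site) <- sites

  lead_adj <- (lead - mu_site[idx, , drop = FALSE]) /
    rho_site[idx, , drop = FALSE]
  scores_adj <- scores
  scores_adj[, seq_len(k)] <- lead_adj
  resid_adj <- scores_adj %*% t(pc$rotation) +
    outer(rep(1, j), pc$center)
  y_adj <- resid_adj + stand_mean

  out <- cohort
  out$features <- y_adj
  rownames(out$features) <- rownames(cohort$features)
  model <- structure(list(
    combat = cb, eigvecs = pc$rotation, eigvals = eigvals,
    center = pc$center, K = k, var_frac = var_frac,
    mu_site = mu_site, rho_site = rho_site, site_labels = sites),
    class = "covbat_model")
  list(cohort = out, model = model)
}

#' @export
print.covbat_model <- function(x, ...) {
  cat(sprintf(
    "<covbat_model> %d sites, %d features; K = %d components (var_frac = %g)\n",
    length(x$site_labels), ncol(x$eigvecs), x$K, x$var_frac))
  invisible(x)
}

#' Tidy a fitted CovBat model
#'
#' One row per site/component combination (corrected components only).
#'
#' @param x a `covbat_model`.
#' @param ... unused.
#' @return A tibble with columns `site`, `component`, `mu`, `rho`.
#' @method tidy covbat_model
#' @export
tidy.covbat_model <- function(x, ...) {
  s <- length(x$site_labels)
  tibble::tibble(
    site = rep(x$site_labels, each = x$K),
    component = rep(seq_len(x$K), times = s),
    mu = as.numeric(t(x$mu_site)),
    rho = as.numeric(t(x$rho_site)))
}

#' @rdname tidy.covbat_model
#' @method glance covbat_model
#' @export
glance.covbat_model <- function(x, ...) {
  tibble::tibble(
    n_sites = length(x$site_labels),
    n_features = ncol(x$eigvecs),
    K = x$K,
    var_frac = x$var_frac,
    var_captured = sum(x$eigvals[seq_len(x$K)]) / sum(x$eigvals))
}
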
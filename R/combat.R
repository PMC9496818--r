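#' Fit the ComBat site-effect model to a cohort
#'
#' Fits the location/scale batch model
#' \deqn{y_{tjv} = \alpha_v + X_{tj}\beta_v + \gamma_{tv} + \delta_{tv}\,\epsilon_{tjv}}
#' by parametric empirical Bayes: per-feature least squares with site effects
#' constrained to a sample-size-weighted zero sum, pooled residual variances,
#' per-site moments of the standardized data, moment-matched normal /
#' inverse-gamma hyperpriors, and iterated conditional posterior means for the
#' shrunken site effects \eqn{\gamma^*_{tv}} (additive) and
#' \eqn{\delta^{*2}_{tv}} (multiplicative, on the variance scale).
#'
#' @param cohort a `conn_cohort` (see [assemble_cohort()]).
#' @param covariates character vector of phenotype columns to protect
#'   (subset of `age`, `sex`, `diagnosis`); their effects are estimated and
#'   restored after site correction. Default: all of them that exist in the
#'   phenotypes.
#' @param eb_tol convergence tolerance for the empirical-Bayes iteration
#'   (maximum absolute parameter change).
#' @param eb_maxit iteration cap.
#' @param eb use empirical-Bayes shrinkage of the site effects (default).
#'   With `eb = FALSE` the raw per-site location/scale estimates are used
#'   directly (no pooling across features).
#' @return A `combat_model`; pass to [apply_combat()], [tidy()] or
#'   [glance()].
#' @references Johnson, Li & Rabinovic's empirical-Bayes batch adjustment,
#'   as standardly applied to neuroimaging feature tables.
#' @export
fit_combat <- function(cohort, covariates = NULL, eb_tol = 1e-4,
                       eb_maxit = 100L, eb = TRUE) {
  stopifnot(inherits(cohort, "conn_cohort"))
  phen <- cohort$phenotypes
  y <- cohort$features
  sites <- sort(unique(phen$site))
  if (length(sites) < 2L) {
    abort("ComBat requires at least 2 sites; the cohort has 1.")
  }
  n_t <- table(factor(phen$site, levels = sites))
  if (any(n_t < 2L)) {
    abort(sprintf("Every site needs >= 2 subjects; offending site(s): %s",
                  paste(names(n_t)[n_t < 2L], collapse = ", ")))
  }
  covariates <- resolve_covariates(phen, covariates)
  design_spec <- make_design_spec(phen, covariates)
  cmat <- build_covariate_matrix(phen, design_spec)

  b <- stats::model.matrix(~ 0 + factor(phen$site, levels = sites))
  colnames(b) <- sites
  x <- cbind(b, cmat)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1L):ncol(x)]]
    abort(sprintf("Design matrix is rank deficient; collinear column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  j <- nrow(y)
  beta_full <- solve(crossprod(x), crossprod(x, y))        # (S+q) x V
  site_coefs <- beta_full[seq_along(sites), , drop = FALSE]
  alpha <- drop(crossprod(as.numeric(n_t) / j, site_coefs)) # weighted grand mean
  beta_cov <- beta_full[-seq_along(sites), , drop = FALSE]

  resid <- y - x %*% beta_full
  var_pooled <- colSums(resid^2) / j
  if (any(var_pooled <= 0)) {
    abort("Some features have zero pooled residual variance; cannot standardize.")
  }
  stand_mean <- outer(rep(1, j), alpha)
  if (ncol(cmat) > 0L) stand_mean <- stand_mean + cmat %*% beta_cov
  z <- (y - stand_mean) / outer(rep(1, j), sqrt(var_pooled))

  gamma_hat <- rowsum(z, phen$site) / as.numeric(n_t[sites])
  delta_hat <- t(vapply(sites, function(s) {
    zs <- z[phen$site == s, , drop = FALSE]
    apply(zs, 2L, var)
  }, numeric(ncol(z))))
  rownames(gamma_hat) <- rownames(delta_hat) <- sites

  eb <- if (eb) {
    eb_shrink(gamma_hat, delta_hat, as.numeric(n_t[sites]),
              tol = eb_tol, maxit = eb_maxit)
  } else {
    list(gamma_star = gamma_hat, delta_star = delta_hat,
         iterations = 0L, converged = TRUE, priors = NULL)
  }

  structure(list(
    alpha = alpha, beta = beta_cov, sigma2 = var_pooled,
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_star = eb$gamma_star, delta_star = eb$delta_star,
    site_labels = sites, n_per_site = as.numeric(n_t[sites]),
    design_spec = design_spec, covariates = covariates,
    eb_iterations = eb$iterations, eb_converged = eb$converged,
    priors = eb$priors),
    class = "combat_model")
}

# covariates defaulting / validation shared by ComBat and CovBat
resolve_covariates <- function(phen, covariates) {
  known <- intersect(c("age", "sex", "diagnosis"), names(phen))
  if (is.null(covariates)) return(known)
  bad <- setdiff(covariates, names(phen))
  if (length(bad) > 0L) {
    abort(sprintf("Covariate(s) not in phenotypes: %s", paste(bad, collapse = ", ")))
  }
  covariates
}

make_design_spec <- function(phen, covariates) {
  lapply(setNames(covariates, covariates), function(cv) {
    col <- phen[[cv]]
    if (is.numeric(col)) list(type = "numeric")
    else list(type = "factor", levels = sort(unique(as.character(col))))
  })
}

build_covariate_matrix <- function(phen, design_spec) {
  cols <- lapply(names(design_spec), function(cv) {
    sp <- design_spec[[cv]]
    col <- phen[[cv]]
    if (sp$type == "numeric") {
      m <- matrix(as.numeric(col), ncol = 1)
      colnames(m) <- cv
      m
    } else {
      vals <- as.character(col)
      unseen <- setdiff(unique(vals), sp$levels)
      if (length(unseen) > 0L) {
        abort(sprintf("Covariate '%s' has level(s) unseen at fit time: %s",
                      cv, paste(unseen, collapse = ", ")))
      }
      lv <- sp$levels
      if (length(lv) < 2L) return(NULL)   # constant factor: no columns
      m <- vapply(lv[-1], function(l) as.numeric(vals == l), numeric(length(vals)))
      m <- matrix(m, nrow = length(vals))
      colnames(m) <- paste0(cv, lv[-1])
      m
    }
  })
  cols <- cols[!vapply(cols, is.null, logical(1))]
  if (length(cols) == 0L) {
    matrix(numeric(0), nrow = nrow(phen), ncol = 0)
  } else do.call(cbind, cols)
}

# Parametric EB shrinkage: normal prior on gamma, inverse-gamma on delta^2,
# hyperparameters by moment matching across features, conditional posterior
# means iterated to convergence.
eb_shrink <- function(gamma_hat, delta_hat, n_t, tol = 1e-4, maxit = 100L) {
  s <- nrow(gamma_hat)
  gamma_bar <- rowMeans(gamma_hat)
  t2 <- apply(gamma_hat, 1L, var)
  d_bar <- rowMeans(delta_hat)
  d_s2 <- apply(delta_hat, 1L, var)
  a_prior <- (2 * d_s2 + d_bar^2) / d_s2
  b_prior <- (d_bar * d_s2 + d_bar^3) / d_s2

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  iterations <- integer(s)
  converged <- logical(s)
  for (t in seq_len(s)) {
    if (!is.finite(t2[t]) || t2[t] <= 0 || !is.finite(d_s2[t]) || d_s2[t] <= 0) {
      # degenerate hyperprior (e.g. too few features): no shrinkage
      converged[t] <- TRUE
      next
    }
    g_old <- gamma_hat[t, ]
    d_old <- delta_hat[t, ]
    n <- n_t[t]
    sum2_base <- (n - 1) * delta_hat[t, ]   # site SS around the site mean
    for (it in seq_len(maxit)) {
      g_new <- (n * t2[t] * gamma_hat[t, ] + d_old * gamma_bar[t]) /
        (n * t2[t] + d_old)
      sum2 <- sum2_base + n * (gamma_hat[t, ] - g_new)^2
      d_new <- (0.5 * sum2 + b_prior[t]) / (n / 2 + a_prior[t] - 1)
      delta_change <- max(abs(g_new - g_old), abs(d_new - d_old))
      g_old <- g_new
      d_old <- d_new
      if (delta_change < tol) break
    }
    gamma_star[t, ] <- g_old
    delta_star[t, ] <- d_old
    iterations[t] <- it
    converged[t] <- delta_change < tol
  }
  list(gamma_star = gamma_star, delta_star = delta_star,
       iterations = max(iterations), converged = all(converged),
       priors = list(gamma_bar = gamma_bar, t2 = t2,
                     a_prior = a_prior, b_prior = b_prior))
}

#' Apply a fitted ComBat model to a cohort
#'
#' Removes the shrunken site location/scale effects and restores the
#' intercept and protected covariate effects:
#' \deqn{y^{ComBat}_{tjv} = \frac{y_{tjv} - \hat\alpha_v - X_{tj}\hat\beta_v -
#'   \gamma^*_{tv}}{\delta^*_{tv}} + \hat\alpha_v + X_{tj}\hat\beta_v.}
#'
#' @param model a `combat_model` from [fit_combat()].
#' @param cohort a `conn_cohort` whose sites and covariate levels were all
#'   seen at fit time (the fitting cohort itself, or held-out subjects).
#' @return A harmonized `conn_cohort` of identical shape and phenotypes.
#' @export
apply_combat <- function(model, cohort) {
  stopifnot(inherits(model, "combat_model"), inherits(cohort, "conn_cohort"))
  phen <- cohort$phenotypes
  unseen <- setdiff(unique(phen$site), model$site_labels)
  if (length(unseen) > 0L) {
    abort(sprintf("Site(s) unseen at fit time: %s", paste(unseen, collapse = ", ")))
  }
  y <- cohort$features
  j <- nrow(y)
  cmat <- build_covariate_matrix(phen, model$design_spec)
  stand_mean <- outer(rep(1, j), model$alpha)
  if (ncol(cmat) > 0L) stand_mean <- stand_mean + cmat %*% model$beta
  z <- (y - stand_mean) / outer(rep(1, j), sqrt(model$sigma2))
  idx <- match(phen$site, model$site_labels)
  z_adj <- (z - model$gamma_star[idx, , drop = FALSE]) /
    sqrt(model$delta_star[idx, , drop = FALSE])
  y_adj <- z_adj * outer(rep(1, j), sqrt(model$sigma2)) + stand_mean
  out <- cohort
  out$features <- y_adj
  rownames(out$features) <- rownames(y)
  out
}

#' @export
print.combat_model <- function(x, ...) {
  cat(sprintf(
    "<combat_model> %d sites x %d features; covariates: %s; EB %sconverged in %d iteration(s)\n",
    length(x$site_labels), length(x$alpha),
    if (length(x$covariates)) paste(x$covariates, collapse = ", ") else "(none)",
    if (x$eb_converged) "" else "NOT ", x$eb_iterations))
  invisible(x)
}

#' Tidy a fitted ComBat model
#'
#' One row per site/feature combination with the raw and shrunken site-effect
#' estimates.
#'
#' @param x a `combat_model`.
#' @param ... unused.
#' @return A tibble with columns `site`, `feature`, `gamma_hat`,
#'   `gamma_star`, `delta_hat`, `delta_star` (standardized scale), plus
#'   `gamma_star_y` (additive effect on the data scale, i.e.
#'   `gamma_star * sqrt(sigma2)`) and `delta_star_sd` (multiplicative effect
#'   as an SD ratio, `sqrt(delta_star)`).
#' @method tidy combat_model
#' @export
tidy.combat_model <- function(x, ...) {
  s <- length(x$site_labels); v <- length(x$alpha)
  tibble::tibble(
    site = rep(x$site_labels, each = v),
    feature = rep(seq_len(v), times = s),
    gamma_hat = as.numeric(t(x$gamma_hat)),
    gamma_star = as.numeric(t(x$gamma_star)),
    delta_hat = as.numeric(t(x$delta_hat)),
    delta_star = as.numeric(t(x$delta_star)),
    gamma_star_y = as.numeric(t(x$gamma_star)) * rep(sqrt(x$sigma2), times = s),
    delta_star_sd = sqrt(as.numeric(t(x$delta_star))))
}

#' @rdname tidy.combat_model
#' @return `glance()`: a one-row tibble with fit-level summaries.
#' @method glance combat_model
#' @export
glance.combat_model <- function(x, ...) {
  tibble::tibble(
    n_sites = length(x$site_labels),
    n_features = length(x$alpha),
    n_subjects = sum(x$n_per_site),
    n_covariate_terms = nrow(x$beta) %||% 0L,
    eb_iterations = x$eb_iterations,
    eb_converged = x$eb_converged)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
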
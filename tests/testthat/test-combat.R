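# Build a cohort whose features carry exactly the effects a test needs.
cohort_with_offsets <- function(seed, n_per = 50, n_rois = 10, offsets = NULL,
                                delta = NULL, noise_sd = 0.25, subject_sd = 0.1) {
  cfg <- sim_config(n_sites = length(offsets %||% delta %||% c(0, 0)),
                    subjects_per_site = n_per, n_rois = n_rois,
                    site_additive_sd = 0, site_multiplicative_range = c(1, 1),
                    diagnosis_effect = 0, subject_sd = subject_sd,
                    noise_sd = noise_sd, link = "identity", seed = seed)
  co <- generate_cohort(cfg)$cohort
  sites <- sort(unique(co$phenotypes$site))
  if (!is.null(offsets)) {
    co$features <- co$features + offsets[match(co$phenotypes$site, sites)]
  }
  if (!is.null(delta)) {
    for (k in seq_along(sites)) {
      r <- co$phenotypes$site == sites[k]
      mu <- colMeans(co$features[r, , drop = FALSE])
      co$features[r, ] <- sweep(co$features[r, , drop = FALSE], 2, mu) *
        delta[k] + rep(mu, each = sum(r))
    }
  }
  co
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("ComBat rejects degenerate designs", {
  g <- generate_cohort(sim_config(n_sites = 2, subjects_per_site = 5,
                                  n_rois = 6, seed = 1))
  one_site <- g$cohort
  one_site$phenotypes$site <- "only"
  expect_error(fit_combat(one_site), "at least 2 sites")

  collinear <- g$cohort
  collinear$phenotypes$age <- ifelse(collinear$phenotypes$sex == "M", 1, 0)
  expect_error(fit_combat(collinear), "rank deficient")

  tiny <- g$cohort
  tiny$phenotypes$site[1:9] <- "A"
  tiny$phenotypes$site[10] <- "B"
  expect_error(fit_combat(tiny), ">= 2 subjects")
})

test_that("ComBat recovers known additive site offsets", {
  co <- cohort_with_offsets(11, n_per = 50, offsets = c(-0.3, 0.3))
  fit <- fit_combat(co)
  est <- tidy(fit) |>
    dplyr::group_by(site) |>
    dplyr::summarise(g = mean(gamma_star_y))
  expect_equal(est$g, c(-0.3, 0.3), tolerance = 0.05 / 0.3)
  expect_true(all(tidy(fit)$delta_star > 0))
})

test_that("ComBat recovers known multiplicative site scales", {
  delta <- c(0.5, 2.0)
  co <- cohort_with_offsets(12, n_per = 100, n_rois = 12, delta = delta,
                            subject_sd = 0)
  fit <- fit_combat(co)
  # delta is identified up to the pooled-variance normalization
  # (weighted mean delta^2 = 1); undo it with the generating values
  scale_back <- sqrt(mean(delta^2))
  est <- tidy(fit) |>
    dplyr::group_by(site) |>
    dplyr::summarise(d = mean(delta_star_sd) * scale_back)
  expect_equal(est$d, delta, tolerance = 0.15)
})

test_that("ComBat is a near-identity when no site effects were injected", {
  # quiet null cohort: the residual perturbation is EB scale-estimation
  # noise times the largest standardized residuals, about 0.2 * noise_sd
  co <- cohort_with_offsets(13, n_per = 100, subject_sd = 0, noise_sd = 0.05)
  out <- apply_combat(fit_combat(co), co)
  expect_lt(max(abs(out$features - co$features)), 0.02)
  expect_identical(out$phenotypes, co$phenotypes)
})

test_that("ComBat closes the site mean gap while preserving diagnosis effects", {
  cfg <- sim_config(n_sites = 2, subjects_per_site = 100, n_rois = 10,
                    site_additive_sd = 0.3, diagnosis_effect = 0.2,
                    link = "identity", seed = 14)
  g <- generate_cohort(cfg)
  co <- g$cohort
  fit <- fit_combat(co)
  out <- apply_combat(fit, co)

  site_gap <- function(x) {
    s <- co$phenotypes$site
    mean(abs(colMeans(x[s == "site01", ]) - colMeans(x[s == "site02", ])))
  }
  expect_lt(site_gap(out$features), 0.1 * site_gap(co$features))

  dx_gap <- function(x) {
    d <- co$phenotypes$diagnosis
    ed <- g$truth$diagnosis_edges
    mean(colMeans(x[d == "patient", ed, drop = FALSE]) -
           colMeans(x[d == "control", ed, drop = FALSE]))
  }
  expect_equal(dx_gap(out$features), dx_gap(co$features), tolerance = 0.2)
})

test_that("pooled feature means survive intercept-only ComBat", {
  co <- cohort_with_offsets(15, n_per = 30, offsets = c(-0.2, 0.2))
  # the exact algebraic identity holds for the raw location/scale form;
  # empirical-Bayes shrinkage trades it for stability
  fit <- fit_combat(co, covariates = character(0), eb = FALSE)
  out <- apply_combat(fit, co)
  expect_equal(colMeans(out$features), colMeans(co$features), tolerance = 1e-6)
})

test_that("without shrinkage ComBat reduces to the location/scale closed form", {
  co <- cohort_with_offsets(16, n_per = 5, n_rois = 3, offsets = c(-0.4, 0.4))
  fit <- fit_combat(co, covariates = character(0), eb = FALSE)
  out <- apply_combat(fit, co)

  # brute-force location/scale adjustment, one feature at a time
  y <- co$features; s <- co$phenotypes$site
  sites <- sort(unique(s)); n_t <- table(factor(s, sites))
  brute <- y
  for (v in seq_len(ncol(y))) {
    site_means <- tapply(y[, v], s, mean)
    alpha <- sum(site_means * n_t) / sum(n_t)
    sigma2 <- mean((y[, v] - site_means[s])^2)
    z <- (y[, v] - alpha) / sqrt(sigma2)
    gam <- tapply(z, s, mean)
    del <- tapply(z, s, var)
    brute[, v] <- (z - gam[s]) / sqrt(del[s]) * sqrt(sigma2) + alpha
  }
  expect_equal(out$features, brute, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("ComBat agrees with the reference empirical-Bayes implementation", {
  skip_if_not_installed("sva")
  g <- generate_cohort(sim_config(n_sites = 3, subjects_per_site = 20,
                                  n_rois = 8, link = "identity", seed = 4))
  co <- g$cohort
  mm <- stats::model.matrix(~ age + sex + diagnosis, data = co$phenotypes)
  ref <- suppressMessages(
    sva::ComBat(dat = t(co$features), batch = co$phenotypes$site, mod = mm))
  mine <- apply_combat(fit_combat(co), co)
  expect_equal(mine$features, t(ref), tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("applying to an unseen site or covariate level fails loudly", {
  co <- cohort_with_offsets(17, n_per = 10)
  fit <- fit_combat(co)
  other <- co
  other$phenotypes$site[1] <- "siteXX"
  expect_error(apply_combat(fit, other), "unseen")
  lvl <- co
  lvl$phenotypes$sex[1] <- "X"
  expect_error(apply_combat(fit, lvl), "unseen")
})

test_that("ComBat models survive a JSON round trip", {
  co <- cohort_with_offsets(18, n_per = 10, n_rois = 6, offsets = c(-0.2, 0.2))
  fit <- fit_combat(co)
  p <- withr::local_tempfile(fileext = ".json")
  write_harmonization_model(fit, p)
  fit2 <- read_harmonization_model(p)
  expect_equal(apply_combat(fit2, co)$features, apply_combat(fit, co)$features,
               tolerance = 1e-12)
})
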
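#' Simulation configuration for synthetic multi-site cohorts
#'
#' Collects every knob of the cohort simulator in one validated object. Site
#' effects are simulated on the Fisher-z scale and (by default) mapped back
#' through tanh so edge features stay in (-1, 1) like phase-interaction
#' values.
#'
#' @param n_sites number of acquisition sites.
#' @param subjects_per_site subjects per site in the main cohort.
#' @param n_rois number of ROIs N (features are the N(N-1)/2 edges).
#' @param timepoints,tr time-series length and repetition time (seconds),
#'   used by [generate_time_series_cohort()].
#' @param site_additive_sd SD of the per-feature additive site effects
#'   (Fisher-z scale). Each site draws a common level shift with this SD plus
#'   per-edge jitter with half this SD; effects are centered across sites.
#' @param site_multiplicative_range log-uniform bounds for the per-site noise
#'   scale delta (multiplicative site effect).
#' @param diagnosis_effect mean shift added on the diagnosis edge subset for
#'   patients.
#' @param diagnosis_fraction share of patients at each site.
#' @param age_effect slope per year of age (applied to all edges, age
#'   centered at 40).
#' @param sex_effect shift applied to all edges for one sex level.
#' @param subject_sd SD of the per-subject scalar factor.
#' @param noise_sd SD of the per-edge measurement noise (before the per-site
#'   multiplicative scale).
#' @param site_lag_sd SD (radians) of per-site phase-lag perturbations in
#'   time-series mode.
#' @param ts_noise_sd SD of additive white noise in time-series mode.
#' @param link `"tanh"` (map Fisher-z features into (-1,1); default) or
#'   `"identity"` (leave features on the linear scale, e.g. for studying the
#'   harmonization models under their own assumptions).
#' @param seed integer fixing all randomness.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 4L, subjects_per_site = 40L, n_rois = 16L,
                       timepoints = 180L, tr = 2.0,
                       site_additive_sd = 0.2,
                       site_multiplicative_range = c(0.8, 1.25),
                       diagnosis_effect = 0.15, diagnosis_fraction = 0.4,
                       age_effect = 0.002, sex_effect = 0.05,
                       subject_sd = 0.1, noise_sd = 0.25,
                       site_lag_sd = 0.3, ts_noise_sd = 0.1,
                       link = c("tanh", "identity"), seed = 1L) {
  link <- match.arg(link)
  stopifnot(n_sites >= 2L, subjects_per_site >= 2L, n_rois >= 3L,
            timepoints >= 3L, tr > 0,
            site_additive_sd >= 0, noise_sd >= 0, subject_sd >= 0,
            length(site_multiplicative_range) == 2L,
            all(site_multiplicative_range > 0),
            diff(site_multiplicative_range) >= 0,
            diagnosis_fraction >= 0, diagnosis_fraction <= 1)
  structure(list(
    n_sites = as.integer(n_sites),
    subjects_per_site = as.integer(subjects_per_site),
    n_rois = as.integer(n_rois), timepoints = as.integer(timepoints),
    tr = tr, site_additive_sd = site_additive_sd,
    site_multiplicative_range = site_multiplicative_range,
    diagnosis_effect = diagnosis_effect,
    diagnosis_fraction = diagnosis_fraction,
    age_effect = age_effect, sex_effect = sex_effect,
    subject_sd = subject_sd, noise_sd = noise_sd,
    site_lag_sd = site_lag_sd, ts_noise_sd = ts_noise_sd,
    link = link, seed = as.integer(seed)),
    class = "sim_config")
}

sim_link <- function(z, link) if (link == "tanh") tanh(z) else z

# shared fixed structure drawn from the seed: base connectome, site effects,
# diagnosis edge subset
sim_structure <- function(cfg) {
  v <- cfg$n_rois * (cfg$n_rois - 1L) / 2L
  base_z <- rnorm(v, mean = 0.6, sd = 0.5)
  n_diag <- max(1L, floor(0.10 * v))
  diagnosis_edges <- seq_len(n_diag)
  site_level <- rnorm(cfg$n_sites, 0, cfg$site_additive_sd)
  gamma <- outer(site_level, rep(1, v)) +
    matrix(rnorm(cfg$n_sites * v, 0, cfg$site_additive_sd / 2),
           cfg$n_sites, v)
  gamma <- sweep(gamma, 2L, colMeans(gamma))   # centered: deviations from the cross-site mean
  r <- cfg$site_multiplicative_range
  delta <- exp(runif(cfg$n_sites, log(r[1]), log(r[2])))
  list(v = v, base_z = base_z, diagnosis_edges = diagnosis_edges,
       gamma = gamma, delta = delta)
}

#' Generate a synthetic multi-site cohort with known ground truth
#'
#' Edge features are built on the Fisher-z scale as base connectome +
#' covariate effects + additive site effect + per-subject factor + site-scaled
#' noise, then mapped through the configured link. The generating site
#' effects, the diagnosis edge subset and the per-subject factors are
#' returned so recovery can be tested.
#'
#' @param cfg a [sim_config()].
#' @return A list with `cohort` (a `conn_cohort`) and `truth` (fields
#'   `gamma_true` sites x features, `delta_true` per-site noise scales,
#'   `m_true` = `gamma_true` — the measurement bias a traveling design
#'   estimates —, `diagnosis_edges`, `subject_factors`, `base_z`).
#' @export
generate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  st <- sim_structure(cfg)
  sites <- sprintf("site%02d", seq_len(cfg$n_sites))
  j <- cfg$n_sites * cfg$subjects_per_site

  phen <- tibble::tibble(
    subject_id = sprintf("sub%04d", seq_len(j)),
    site = rep(sites, each = cfg$subjects_per_site),
    age = round(runif(j, 18, 65), 1),
    sex = sample(c("F", "M"), j, replace = TRUE),
    diagnosis = ifelse(rbinom(j, 1, cfg$diagnosis_fraction) == 1,
                       "patient", "control"),
    tr = cfg$tr)
  # keep both diagnosis levels present per site so the design stays full rank
  for (s in sites) {
    rows <- which(phen$site == s)
    if (length(unique(phen$diagnosis[rows])) < 2L && cfg$diagnosis_fraction > 0) {
      phen$diagnosis[rows[1]] <- "patient"
      phen$diagnosis[rows[2]] <- "control"
    }
  }

  subject_factors <- rnorm(j, 0, cfg$subject_sd)
  site_idx <- match(phen$site, sites)
  z <- outer(rep(1, j), st$base_z) +
    st$gamma[site_idx, , drop = FALSE] +
    cfg$age_effect * (phen$age - 40) +
    cfg$sex_effect * (phen$sex == "M") +
    subject_factors +
    st$delta[site_idx] * matrix(rnorm(j * st$v, 0, cfg$noise_sd), j, st$v)
  patients <- phen$diagnosis == "patient"
  z[patients, st$diagnosis_edges] <- z[patients, st$diagnosis_edges] +
    cfg$diagnosis_effect

  cohort <- new_conn_cohort(sim_link(z, cfg$link), phen, n_rois = cfg$n_rois)
  truth <- list(gamma_true = st$gamma, delta_true = st$delta,
                m_true = st$gamma, diagnosis_edges = st$diagnosis_edges,
                subject_factors = subject_factors, base_z = st$base_z,
                site_labels = sites)
  list(cohort = cohort, truth = truth)
}

#' Generate the traveling-subject companion of a synthetic cohort
#'
#' The same healthy travelers are "scanned" once at every site, sharing the
#' main cohort's measurement biases `m_true`; each traveler's subject factor
#' is constant across all of their scans.
#'
#' @param cfg the [sim_config()] the main cohort was generated with.
#' @param truth the `truth` component returned by [generate_cohort()].
#' @param n_travelers number of traveling participants (>= 2).
#' @return A `conn_cohort` with `n_travelers * n_sites` rows; phenotype
#'   column `traveler_id` identifies the repeated participants.
#' @export
generate_traveling_companion <- function(cfg, truth, n_travelers = 9L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_travelers < 2L) abort("A traveling design needs >= 2 travelers.")
  set.seed(cfg$seed + 777L)
  sites <- truth$site_labels
  v <- length(truth$base_z)
  trav <- sprintf("trav%02d", seq_len(n_travelers))
  p_fac <- rnorm(n_travelers, 0, cfg$subject_sd)
  age <- round(runif(n_travelers, 22, 55), 1)
  sex <- sample(c("F", "M"), n_travelers, replace = TRUE)

  grid <- expand.grid(traveler = seq_len(n_travelers),
                      site = seq_len(length(sites)))
  z <- outer(rep(1, nrow(grid)), truth$base_z) +
    truth$m_true[grid$site, , drop = FALSE] +
    p_fac[grid$traveler] +
    truth$delta_true[grid$site] *
      matrix(rnorm(nrow(grid) * v, 0, cfg$noise_sd), nrow(grid), v)

  phen <- tibble::tibble(
    subject_id = paste0(trav[grid$traveler], "_", sites[grid$site]),
    traveler_id = trav[grid$traveler],
    site = sites[grid$site],
    age = age[grid$traveler], sex = sex[grid$traveler],
    diagnosis = "control", tr = cfg$tr)
  new_conn_cohort(sim_link(z, cfg$link), phen, n_rois = cfg$n_rois)
}

#' Generate a multi-site cohort of narrow-band time series
#'
#' Exercises the full connectivity pipeline: each ROI gets a sinusoid inside
#' the 0.04--0.07 Hz pass band whose phase offset encodes the target
#' connectome (the phase-interaction value of an edge with constant lag
#' d is cos(d)); site effects enter as per-site lag perturbations, and white
#' noise is added on top.
#'
#' @param cfg a [sim_config()] with `timepoints >= 64`.
#' @param roi_lags optional vector of N phase offsets (radians) shared by all
#'   subjects; by default offsets are drawn uniformly per cohort.
#' @return A list with `series` (list of [subject_ts()]) and `phenotypes`
#'   (tibble with subject_id, site, age, sex, diagnosis, tr).
#' @export
generate_time_series_cohort <- function(cfg = sim_config(), roi_lags = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$timepoints < 64L) abort("Time-series mode requires timepoints >= 64.")
  set.seed(cfg$seed + 333L)
  n <- cfg$n_rois
  sites <- sprintf("site%02d", seq_len(cfg$n_sites))
  if (is.null(roi_lags)) roi_lags <- runif(n, 0, 2 * pi)
  if (length(roi_lags) != n) abort("`roi_lags` must have length n_rois.")
  site_lag <- matrix(rnorm(cfg$n_sites * n, 0, cfg$site_lag_sd), cfg$n_sites, n)

  j <- cfg$n_sites * cfg$subjects_per_site
  phen <- tibble::tibble(
    subject_id = sprintf("ts%04d", seq_len(j)),
    site = rep(sites, each = cfg$subjects_per_site),
    age = round(runif(j, 18, 65), 1),
    sex = sample(c("F", "M"), j, replace = TRUE),
    diagnosis = ifelse(rbinom(j, 1, cfg$diagnosis_fraction) == 1,
                       "patient", "control"),
    tr = cfg$tr)
  tgrid <- (seq_len(cfg$timepoints) - 1L) * cfg$tr
  series <- lapply(seq_len(j), function(i) {
    s <- match(phen$site[i], sites)
    f <- runif(1, 0.048, 0.062)
    vals <- vapply(seq_len(n), function(r) {
      sin(2 * pi * f * tgrid + roi_lags[r] + site_lag[s, r]) +
        rnorm(cfg$timepoints, 0, cfg$ts_noise_sd)
    }, numeric(cfg$timepoints))
    subject_ts(vals, subject_id = phen$subject_id[i], tr = cfg$tr)
  })
  list(series = series, phenotypes = phen)
}
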
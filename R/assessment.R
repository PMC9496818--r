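#' Kruskal-Wallis test of a site effect
#'
#' Rank-based k-sample test of the null hypothesis that the population median
#' of all sites is equal, with tie correction, p-value from the chi-square
#' approximation with (number of sites - 1) degrees of freedom (via
#' [stats::kruskal.test()]).
#'
#' @param values numeric vector of per-subject measurements (H or F).
#' @param groups site labels, same length as `values`.
#' @return A one-row tibble: `h_statistic`, `df`, `p_value`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.character(groups)
  if (length(values) != length(groups)) {
    abort("`values` and `groups` must have equal length.")
  }
  counts <- table(groups)
  if (length(counts) < 2L) abort("At least 2 groups are required.")
  small <- names(counts)[counts < 2L]
  if (length(small) > 0L) {
    abort(sprintf("Group(s) with fewer than 2 observations: %s",
                  paste(small, collapse = ", ")))
  }
  kt <- kruskal.test(values, factor(groups))
  tibble::tibble(h_statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_value = unname(kt$p.value))
}

#' The p' = -log10(p) transform
#'
#' Puts p-values on a scale where larger means a stronger residual site
#' effect; p' <= 1.301 corresponds to p >= 0.05 (no significant effect).
#'
#' @param p p-value(s) in (0, 1].
#' @return -log10(p).
#' @export
neg_log_transform <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  -log10(p)
}

#' Significance cut-off on the p' scale (p = 0.05)
#' @export
P_PRIME_CUTOFF <- -log10(0.05)

#' Assess residual site effects on the Shannon-Fisher coordinates
#'
#' Runs the Kruskal-Wallis site test twice — once on the entropy coordinate
#' (measure SE) and once on the Fisher coordinate (measure FI) — and reports
#' both on the p' scale. A row is significant (residual site effect) when
#' p' > 1.301, i.e. p < 0.05.
#'
#' @param points a tibble of plane points from [shannon_fisher_points()]
#'   (columns `site`, `H`, `F`).
#' @param variant label for the harmonization variant the points came from
#'   (e.g. `"unharmonized"`, `"combat"`, `"covbat"`, `"traveling"`).
#' @param bonferroni if `TRUE`, multiply p-values by the number of tests (2)
#'   before transforming. Off by default.
#' @return A tibble with two rows (SE, FI) and columns `variant`, `measure`,
#'   `h_statistic`, `p_value`, `p_prime`, `significant`, `n_sites`,
#'   `n_subjects`.
#' @export
assess_cohort <- function(points, variant = "unharmonized",
                          bonferroni = FALSE) {
  stopifnot(is.data.frame(points), all(c("site", "H", "F") %in% names(points)))
  if (length(unique(points$site)) < 2L) {
    abort("Assessment requires points from at least 2 sites.")
  }
  one <- function(vals, measure) {
    kw <- kruskal_wallis(vals, points$site)
    p <- kw$p_value
    if (bonferroni) p <- min(1, 2 * p)
    tibble::tibble(variant = variant, measure = measure,
                   h_statistic = kw$h_statistic, p_value = p,
                   p_prime = neg_log_transform(p),
                   significant = neg_log_transform(p) > P_PRIME_CUTOFF,
                   n_sites = length(unique(points$site)),
                   n_subjects = nrow(points))
  }
  dplyr::bind_rows(one(points$H, "SE"), one(points$F, "FI"))
}

#' Re-run the assessment across a sweep of binarization thresholds
#'
#' The binarization threshold is a nuisance choice; verdicts should be stable
#' over a wide range (roughly 0.2--0.8). This helper recomputes plane points
#' and the site-effect assessment at each threshold.
#'
#' @param cohort a `conn_cohort` (typically one harmonization variant).
#' @param thresholds numeric vector of thresholds.
#' @param variant variant label passed through to [assess_cohort()].
#' @return A tibble: the [assess_cohort()] output stacked over thresholds,
#'   with a `threshold` column.
#' @export
threshold_sweep <- function(cohort, thresholds = seq(0.2, 0.8, by = 0.1),
                            variant = "unharmonized") {
  purrr::map_dfr(thresholds, function(th) {
    pts <- shannon_fisher_points(cohort, threshold = th)
    dplyr::mutate(assess_cohort(pts, variant = variant), threshold = th,
                  .before = 1L)
  })
}

#' Scatter the cohort on the Shannon-Fisher plane
#'
#' One point per subject, colored by acquisition site; axes are the unit
#' square the (H, F) coordinates live in. Color assignment is deterministic
#' (sites sorted alphabetically).
#'
#' @param points tibble from [shannon_fisher_points()].
#' @param title optional plot title.
#' @return A ggplot object.
#' @export
plot_plane <- function(points, title = NULL) {
  stopifnot(is.data.frame(points))
  if (nrow(points) == 0L) abort("No plane points to plot.")
  points <- dplyr::mutate(points,
                          site = factor(.data$site, levels = sort(unique(.data$site))))
  ggplot2::ggplot(points, ggplot2::aes(x = .data$H, y = .data$F,
                                       colour = .data$site)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1), expand = FALSE) +
    ggplot2::labs(x = "Normalized network Shannon entropy (H)",
                  y = "Normalized network Fisher information (F)",
                  colour = "Site", title = title) +
    ggplot2::theme_minimal()
}

#' @rdname plot_plane
#' @param object,... for the `autoplot()` method: a plane-point tibble and
#'   arguments passed to [plot_plane()].
#' @importFrom ggplot2 autoplot
#' @method autoplot sf_plane
#' @export
autoplot.sf_plane <- function(object, ...) plot_plane(object, ...)

#' Write the assessment report as CSV and a text table
#'
#' @param results stacked [assess_cohort()] tibbles (several variants).
#' @param path output CSV path; a sibling `<path>.txt` holds the rendered
#'   table.
#' @return `path`, invisibly.
#' @export
write_assessment_report <- function(results, path) {
  out <- dplyr::mutate(results,
                       dplyr::across(dplyr::where(is.numeric), ~ round(.x, 6)))
  utils::write.csv(out, path, row.names = FALSE)
  wide <- tidyr::pivot_wider(
    dplyr::select(results, dplyr::any_of(c("threshold", "variant", "measure", "p_prime"))),
    names_from = "variant", values_from = "p_prime")
  txt <- c("Transformed p-values (p' = -log10 p) of the Kruskal-Wallis site test",
           sprintf("significance cut-off: p' > %.3f (p < 0.05)", P_PRIME_CUTOFF),
           "", utils::capture.output(print(as.data.frame(wide), row.names = FALSE)))
  writeLines(txt, paste0(path, ".txt"))
  invisible(path)
}
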
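#' Save / load a fitted harmonization model
#'
#' Serializes a `combat_model`, `covbat_model` or `traveling_model` to a
#' single JSON bundle (numeric arrays stored at full precision), so a model
#' fitted once can be re-applied to held-out subjects in a later session.
#'
#' @param model a fitted harmonization model.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_harmonization_model <- function(model, path) {
  kind <- class(model)[1]
  if (!kind %in% c("combat_model", "covbat_model", "traveling_model")) {
    abort("Not a harmonization model.")
  }
  payload <- list(kind = kind, fields = unclass_deep(model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", matrix = "rowmajor")
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    lapply(unclass(x), unclass_deep)
  } else x
}

#' @rdname write_harmonization_model
#' @export
read_harmonization_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  f <- payload$fields
  restore_mat <- function(m, rn = NULL) {
    m <- as.matrix(m)
    if (!is.null(rn)) rownames(m) <- rn
    m
  }
  model <- switch(payload$kind,
    combat_model = {
      f$gamma_hat <- restore_mat(f$gamma_hat, f$site_labels)
      f$delta_hat <- restore_mat(f$delta_hat, f$site_labels)
      f$gamma_star <- restore_mat(f$gamma_star, f$site_labels)
      f$delta_star <- restore_mat(f$delta_star, f$site_labels)
      f$beta <- if (length(f$beta) == 0) {
        matrix(numeric(0), 0, length(f$alpha))
      } else restore_mat(f$beta)
      f$design_spec <- lapply(f$design_spec, as.list)
      f
    },
    covbat_model = {
      f$combat <- restore_combat(f$combat)
      f$eigvecs <- restore_mat(f$eigvecs)
      f$mu_site <- restore_mat(f$mu_site, f$site_labels)
      f$rho_site <- restore_mat(f$rho_site, f$site_labels)
      f
    },
    traveling_model = {
      f$m_hat <- restore_mat(f$m_hat, f$site_labels)
      f$p_hat <- restore_mat(f$p_hat, f$travelers)
      if (!is.null(f$d_hat) && length(f$d_hat) > 0) {
        f$d_hat <- restore_mat(f$d_hat, f$diagnoses)
      } else f["d_hat"] <- list(NULL)
      f
    },
    abort(sprintf("Unknown model kind '%s'.", payload$kind)))
  structure(model, class = payload$kind)
}

restore_combat <- function(f) {
  f$gamma_hat <- `rownames<-`(as.matrix(f$gamma_hat), f$site_labels)
  f$delta_hat <- `rownames<-`(as.matrix(f$delta_hat), f$site_labels)
  f$gamma_star <- `rownames<-`(as.matrix(f$gamma_star), f$site_labels)
  f$delta_star <- `rownames<-`(as.matrix(f$delta_star), f$site_labels)
  f$beta <- if (length(f$beta) == 0) {
    matrix(numeric(0), 0, length(f$alpha))
  } else as.matrix(f$beta)
  f$design_spec <- lapply(f$design_spec, as.list)
  structure(f, class = "combat_model")
}
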
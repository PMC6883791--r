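#' Tidy an elasticity fit into per-mode estimates
#'
#' @param x An [estimate_elasticity()] result.
#' @param ... Unused.
#' @return A tibble with one row per deformation mode (`axial`, `radial`)
#'   plus the combined estimate: `term`, `estimate` (MPa), `strain`.
#' @export
tidy.elasticity_fit <- function(x, ...) {
  e <- x$estimate
  tibble(
    term = c("axial", "radial", "combined"),
    estimate = c(e$E_axial, e$E_radial, e$E),
    strain = c(e$strain_h, e$strain_r, NA_real_)
  )
}

#' One-row summary of an elasticity fit
#'
#' @inheritParams tidy.elasticity_fit
#' @return A one-row tibble: `E`, `sd`, `E_axial`, `E_radial` (MPa),
#'   `h_avg`, `dh`, `r_avg`, `dr` (nm), `V_nm3`, `temperature`,
#'   `n_windows`, `n_frames`.
#' @export
glance.elasticity_fit <- function(x, ...) {
  dplyr::bind_cols(
    x$estimate[, c("E", "sd", "E_axial", "E_radial", "h_avg", "dh",
                   "r_avg", "dr", "V_nm3", "temperature")],
    tibble(n_windows = x$params$n_windows, n_frames = x$params$n_frames)
  )
}

#' Tidy a Hertz fit
#'
#' @param x A [fit_hertz()] result.
#' @param ... Unused.
#' @return A one-row tibble of the fitted quantities.
#' @export
tidy.hertz_fit <- function(x, ...) {
  tibble(
    term = c("E_MPa", "prefactor_pN_nm32", "contact_nm", "baseline_pN"),
    estimate = c(x$E, x$a, x$contact_nm, x$baseline_pN)
  )
}

#' One-row summary of a Hertz fit
#'
#' @inheritParams tidy.hertz_fit
#' @return A one-row tibble: `E` (MPa), `contact_nm`, `baseline_pN`,
#'   `residual_rms_pN`, `n_points`, `nu`, `R`, `delta_max`, `F_max`.
#' @export
glance.hertz_fit <- function(x, ...) {
  tibble(
    E = x$E, contact_nm = x$contact_nm, baseline_pN = x$baseline_pN,
    residual_rms_pN = x$residual_rms_pN, n_points = x$n_points,
    nu = x$nu, R = x$R, delta_max = x$delta_max, F_max = x$F_max
  )
}

#' Tidy a trajectory PCA into a variance table
#'
#' @param x A [pca_modes()] result.
#' @param ... Unused.
#' @return A tibble: `component`, `variance_nm2`, `fraction`, `cumulative`.
#' @export
tidy.traj_pca <- function(x, ...) {
  v <- x$variances
  tibble(
    component = seq_along(v),
    variance_nm2 = v,
    fraction = v / sum(v),
    cumulative = cumsum(v) / sum(v)
  )
}

#' One-row summary of a cluster report
#'
#' @param x A [count_clusters()] result.
#' @param ... Unused.
#' @return A one-row tibble: `n_particles`, `n_clusters`, `largest`,
#'   `fraction_clustered`, `radius_um`.
#' @export
glance.cluster_report <- function(x, ...) {
  parts <- attr(x, "particles")
  tibble(
    n_particles = nrow(parts),
    n_clusters = nrow(x),
    largest = if (nrow(x)) max(x$size) else 0L,
    fraction_clustered = fraction_clustered(x),
    radius_um = attr(x, "radius_um")
  )
}
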
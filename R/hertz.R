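# --- Forward model ------------------------------------------------------

#' Hertz force for a rigid sphere indenting an elastic half-space
#'
#' The spherical-indenter Hertz relation, written force-explicit:
#' `F = (4/3) * E / (1 - nu^2) * sqrt(R) * delta^(3/2)`. With E in MPa, R
#' and delta in nm, F comes out in pN directly (1 MPa = 1 pN/nm^2).
#'
#' @param delta Indentation depth(s), nm (>= 0).
#' @param E Young's modulus, MPa (> 0).
#' @param nu Poisson ratio, in `[0, 0.5)`; default 1/3.
#' @param R Tip radius, nm (> 0); default 10.
#' @return Force(s) in pN.
#' @examples
#' hertz_force(1.5, E = 10) # ~87 pN
#' @export
hertz_force <- function(delta, E, nu = 1 / 3, R = 10) {
  if (any(delta < 0)) abort("indentation depth must be >= 0.")
  if (E <= 0 || R <= 0) abort("E and R must be positive.")
  if (nu < 0 || nu >= 0.5) abort("Poisson ratio must lie in [0, 0.5).")
  (4 / 3) * E / (1 - nu^2) * sqrt(R) * delta^1.5
}

# Prefactor a (pN / nm^(3/2)) -> modulus (MPa), and back.
.hertz_E_from_a <- function(a, nu, R) a * 3 * (1 - nu^2) / (4 * sqrt(R))

# --- Contact point ------------------------------------------------------

#' Detect the tip-sample contact point of an approach curve
#'
#' Deterministic piecewise grid search: for every candidate contact index,
#' the pre-contact segment is fit by a flat baseline and the post-contact
#' segment by the Hertz power law `F = baseline + a * delta^(3/2)` (linear
#' in `a`); the candidate minimising the total squared residual wins. If no
#' candidate with a positive prefactor improves on a flat line by at least
#' `min_improvement` (fractional RSS reduction), there is no contact in the
#' curve.
#'
#' @param curve A [force_curve()] (approach segment, >= 20 points).
#' @param min_baseline Minimum number of pre-contact points (default 10).
#' @param min_improvement Minimum fractional RSS improvement over a flat fit
#'   (default 0.05).
#' @return A one-row tibble: `contact_nm`, `baseline_pN`, `index`, `rss`.
#' @export
detect_contact_point <- function(curve, min_baseline = 10, min_improvement = 0.05) {
  d <- curve$displacement_nm
  f <- curve$force_pN
  n <- length(d)
  if (n < 20L) abort("contact detection needs at least 20 points.")
  flat_rss <- sum((f - mean(f))^2)
  best <- list(rss = Inf, i = NA_integer_, baseline = NA_real_)
  for (i in seq(min_baseline, n - 5L)) {
    b <- mean(f[1:i])
    post <- (i + 1L):n
    u <- (d[post] - d[i])^1.5
    fp <- f[post] - b
    a <- sum(u * fp) / sum(u^2)
    if (!is.finite(a) || a <= 0) next
    rss <- sum((f[1:i] - b)^2) + sum((fp - a * u)^2)
    if (rss < best$rss) best <- list(rss = rss, i = i, baseline = b, a = a)
  }
  if (!is.finite(best$rss) ||
      flat_rss <= 0 ||
      (flat_rss - best$rss) / flat_rss < min_improvement) {
    abort("no contact detected: no piecewise fit improves on a flat baseline.")
  }
  tibble(
    contact_nm = d[best$i], baseline_pN = best$baseline,
    index = best$i, rss = best$rss
  )
}

# --- Hertz fit ----------------------------------------------------------

#' Fit the Hertz spherical-indenter model to a force curve
#'
#' Converts displacement to indentation at the (given or detected) contact
#' point, restricts to the shallow-indentation window where the half-space
#' model holds (`delta <= delta_max`, `F <= F_max`), and fits the prefactor
#' of `F = a * delta^(3/2)` by ordinary least squares through the origin
#' (linear after the substitution `u = delta^(3/2)`). The modulus follows
#' from `E = 3 a (1 - nu^2) / (4 sqrt(R))`.
#'
#' @param curve A [force_curve()].
#' @param nu Poisson ratio; defaults to the curve's metadata, else 1/3.
#' @param R Tip radius (nm); defaults to the curve's metadata, else 10.
#' @param delta_max Maximum indentation used in the fit, nm (default 1.5).
#' @param F_max Maximum force used in the fit, pN (default 200).
#' @param contact Contact point (nm on the displacement axis); detected with
#'   [detect_contact_point()] when `NULL`.
#' @param baseline Force baseline (pN) subtracted before fitting; estimated
#'   alongside the contact point when `NULL`.
#' @param spring_constant Optional cantilever spring constant (pN/nm). When
#'   supplied, the displacement axis is taken as z-piezo travel and the
#'   indentation is corrected by the cantilever deflection `F / k`.
#'
#' @return An object of class `hertz_fit` with fields `E` (MPa), `a`
#'   (pN/nm^1.5), `contact_nm`, `baseline_pN`, `residual_rms_pN`,
#'   `n_points`, `delta_max`, `F_max`, `nu`, `R`. See [tidy.hertz_fit()].
#' @examples
#' curve <- gen_force_curve(E = 5.8, noise_sd = 0, seed = 1)
#' glance(fit_hertz(curve))$E
#' @export
fit_hertz <- function(curve, nu = NULL, R = NULL, delta_max = 1.5, F_max = 200,
                      contact = NULL, baseline = NULL, spring_constant = NULL) {
  nu <- nu %||% attr(curve, "poisson") %||% (1 / 3)
  R <- R %||% attr(curve, "tip_radius_nm") %||% 10
  if (R <= 0) abort("tip radius must be positive.")
  if (nu < 0 || nu >= 0.5) abort("Poisson ratio must lie in [0, 0.5).")
  if (is.null(contact)) {
    cp <- detect_contact_point(curve)
    contact <- cp$contact_nm
    if (is.null(baseline)) baseline <- cp$baseline_pN
  }
  baseline <- baseline %||% 0
  f <- curve$force_pN - baseline
  delta <- curve$displacement_nm - contact
  if (!is.null(spring_constant)) {
    if (spring_constant <= 0) abort("spring constant must be positive.")
    delta <- delta - f / spring_constant
  }
  keep <- delta > 0 & delta <= delta_max & f <= F_max
  if (sum(keep) < 5L) abort("too few points in the fit window (need >= 5).")
  u <- delta[keep]^1.5
  fk <- f[keep]
  a <- sum(u * fk) / sum(u^2)
  if (!is.finite(a) || a <= 0) abort("negative fitted prefactor: curve is not Hertzian.")
  resid <- fk - a * u
  structure(
    list(
      E = .hertz_E_from_a(a, nu, R), a = a,
      contact_nm = contact, baseline_pN = baseline,
      residual_rms_pN = sqrt(mean(resid^2)),
      n_points = sum(keep), delta_max = delta_max, F_max = F_max,
      nu = nu, R = R
    ),
    class = "hertz_fit"
  )
}

#' @export
print.hertz_fit <- function(x, ...) {
  cat(sprintf(
    "<hertz_fit> E = %.3g MPa (nu = %.3g, R = %g nm); contact %.3g nm, RMS %.2g pN, %d pts\n",
    x$E, x$nu, x$R, x$contact_nm, x$residual_rms_pN, x$n_points
  ))
  invisible(x)
}

# --- Modulus map --------------------------------------------------------

#' Elastic modulus map across positions on a particle
#'
#' Fits every force curve taken at a grid of positions on one particle and
#' summarises elastic uniformity as the max/min modulus ratio. A particle is
#' called uniform when the ratio stays below `bound` (default one order of
#' magnitude, the acceptance band appropriate near the instrument noise
#' floor).
#'
#' @param curves A data frame with a `position` column (any label) and a
#'   `curve` list-column of [force_curve()] objects; or a named list of
#'   force curves.
#' @param bound Acceptance bound on the max/min modulus ratio (default 10).
#' @param ... Passed to [fit_hertz()].
#'
#' @return A tibble of class `modulus_map` with one row per position
#'   (`position`, `E_MPa`, `contact_nm`, `residual_rms_pN`, `n_points`,
#'   `fit_ok`) and the uniformity summary in attributes (`ratio`,
#'   `uniform`, `bound`).
#' @export
modulus_map <- function(curves, bound = 10, ...) {
  if (is.data.frame(curves)) {
    stopifnot(all(c("position", "curve") %in% names(curves)))
    positions <- curves$position
    curve_list <- curves$curve
  } else {
    positions <- names(curves) %||% as.character(seq_along(curves))
    curve_list <- curves
  }
  if (length(curve_list) < 2L) abort("a modulus map needs at least 2 positions.")
  rows <- purrr::map2(positions, curve_list, function(p, cu) {
    fit <- tryCatch(fit_hertz(cu, ...), error = function(e) NULL)
    if (is.null(fit)) {
      tibble(position = p, E_MPa = NA_real_, contact_nm = NA_real_,
             residual_rms_pN = NA_real_, n_points = NA_integer_, fit_ok = FALSE)
    } else {
      tibble(position = p, E_MPa = fit$E, contact_nm = fit$contact_nm,
             residual_rms_pN = fit$residual_rms_pN, n_points = fit$n_points,
             fit_ok = TRUE)
    }
  })
  out <- dplyr::bind_rows(rows)
  if (!any(out$fit_ok)) abort("all fits failed.")
  e <- out$E_MPa[out$fit_ok]
  ratio <- max(e) / min(e)
  class(out) <- c("modulus_map", class(out))
  attr(out, "ratio") <- ratio
  attr(out, "uniform") <- ratio <= bound
  attr(out, "bound") <- bound
  out
}
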
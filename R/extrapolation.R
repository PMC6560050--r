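# Complete-basis-set extrapolation.
#
# Two schemes are implemented:
#   scheme I  : two-point power-law extrapolation of DZ/TZ energies, with
#               separate exponents for the HF (alpha = 4.93) and correlation
#               (beta = 2.13) components.
#   scheme II : X^-3 two-point extrapolation of the TZ/QZ correlation
#               energies; the HF limit from a closed-form three-point
#               exponential fit over DZ/TZ/QZ (or, optionally, from the
#               scheme-I power-law form).
#
# Both two-point formulas are instances of one closed form: if
# E(X) = E_CBS + A * X^(-p), then
# E_CBS = (Xhi^p * Ehi - Xlo^p * Elo) / (Xhi^p - Xlo^p).

#' Extrapolation parameters
#'
#' @param alpha HF power-law exponent for the two-point scheme (default 4.93).
#' @param beta correlation power-law exponent for the two-point scheme
#'   (default 2.13).
#' @param hf_cbs_mode how scheme II obtains its HF limit: `"exponential"`
#'   (three-point exponential fit over DZ/TZ/QZ, the default) or `"eq2"`
#'   (the scheme-I two-point power-law on DZ/TZ with exponent `alpha`).
#' @return A `cbs_params` list.
#' @export
cbs_params <- function(alpha = 4.93, beta = 2.13,
                       hf_cbs_mode = c("exponential", "eq2")) {
  if (!is.numeric(alpha) || alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  if (!is.numeric(beta) || beta <= 0) stop("`beta` must be > 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta,
                 hf_cbs_mode = match.arg(hf_cbs_mode)),
            class = "cbs_params")
}

#' Two-point power-law CBS extrapolation
#'
#' Exact fixed point of `E(X) = E_CBS + A * X^(-p)` through two cardinals:
#' `(xhi^p * e_hi - xlo^p * e_lo) / (xhi^p - xlo^p)`.  The two weights sum
#' to one, so a constant series is its own limit.  With `exponent = 3` and
#' cardinals (3, 4) this is the standard correlation-energy formula.
#'
#' @param e_lo,e_hi [quantity()] energies at the lower/higher cardinal
#'   (same unit).
#' @param x_lo,x_hi cardinal numbers, `x_hi > x_lo >= 2`.
#' @param exponent positive power `p`.
#' @return A `quantity`: the extrapolated CBS energy.
#' @examples
#' two_point_power_cbs(quantity(-0.9, "hartree"), quantity(-0.95, "hartree"),
#'                     3, 4, 3) # (64*(-0.95) - 27*(-0.9)) / 37
#' @export
two_point_power_cbs <- function(e_lo, e_hi, x_lo, x_hi, exponent) {
  if (!is_quantity(e_lo) || !is_quantity(e_hi)) {
    stop("energies must be quantities", call. = FALSE)
  }
  u <- .same_unit(e_lo, e_hi, "two_point_power_cbs")
  if (x_hi == x_lo) stop("cardinals must differ", call. = FALSE)
  if (x_hi < x_lo) stop("`x_hi` must exceed `x_lo`", call. = FALSE)
  if (x_lo < 2) stop("cardinals must be >= 2", call. = FALSE)
  if (!is.numeric(exponent) || exponent <= 0) {
    stop("`exponent` must be > 0", call. = FALSE)
  }
  whi <- x_hi^exponent / (x_hi^exponent - x_lo^exponent)
  wlo <- x_lo^exponent / (x_hi^exponent - x_lo^exponent)
  quantity(whi * qty_value(e_hi) - wlo * qty_value(e_lo), u)
}

#' Three-point exponential CBS extrapolation of the HF energy
#'
#' Closed-form solution of `E(X) = E_CBS + A * exp(-B * X)` through three
#' consecutive cardinals; with `d1 = e_dz - e_tz` and `d2 = e_tz - e_qz` the
#' limit is `e_qz - d2^2 / (d1 - d2)` (the Aitken delta-squared form, exact
#' when the series is exactly exponential).  Requires monotone, decelerating
#' convergence: `d1 * d2 > 0` and `|d2| < |d1|`.
#'
#' @param e_dz,e_tz,e_qz [quantity()] HF energies at cardinals 2, 3, 4
#'   (same unit).
#' @return A `quantity`: the HF/CBS limit.
#' @export
hf_exponential_cbs <- function(e_dz, e_tz, e_qz) {
  if (!is_quantity(e_dz) || !is_quantity(e_tz) || !is_quantity(e_qz)) {
    stop("energies must be quantities", call. = FALSE)
  }
  u <- .same_unit(e_dz, e_tz, "hf_exponential_cbs")
  .same_unit(e_tz, e_qz, "hf_exponential_cbs")
  d1 <- qty_value(e_dz) - qty_value(e_tz)
  d2 <- qty_value(e_tz) - qty_value(e_qz)
  if (d1 * d2 <= 0 || abs(d2) >= abs(d1)) {
    stop("series is not monotonically contracting (d1 = ", format(d1),
         ", d2 = ", format(d2), "); exponential extrapolation undefined",
         call. = FALSE)
  }
  quantity(qty_value(e_qz) - d2^2 / (d1 - d2), u)
}

.new_cbs_result <- function(hf, corr, scheme, inputs, params) {
  structure(list(cbs_hf = hf, cbs_corr = corr, cbs_total = hf + corr,
                 scheme = scheme, inputs_used = inputs, params = params),
            class = "cbs_result")
}

#' Scheme I: two-point DZ/TZ power-law extrapolation
#'
#' HF and correlation components are extrapolated with the two-point
#' power-law at cardinals (2, 3), with exponents `alpha` (HF) and `beta`
#' (correlation).
#'
#' @param e_dz,e_tz [component_energy()] at cardinals 2 and 3.
#' @param params a [cbs_params()].
#' @return A `cbs_result` with `cbs_hf`, `cbs_corr`, `cbs_total`, the scheme
#'   tag and the inputs used.
#' @export
scheme1_cbs <- function(e_dz, e_tz, params = cbs_params()) {
  stopifnot(inherits(e_dz, "component_energy"),
            inherits(e_tz, "component_energy"))
  hf <- two_point_power_cbs(e_dz$hf, e_tz$hf, 2, 3, params$alpha)
  corr <- two_point_power_cbs(e_dz$corr, e_tz$corr, 2, 3, params$beta)
  .new_cbs_result(hf, corr, "scheme1",
                  list(`2` = e_dz, `3` = e_tz), params)
}

#' Scheme II: X^-3 correlation + exponential HF extrapolation
#'
#' The correlation limit comes from the two-point X^-3 formula at cardinals
#' (3, 4); the HF limit from [hf_exponential_cbs()] over all three cardinals
#' (or from the scheme-I power-law if `params$hf_cbs_mode == "eq2"`).
#'
#' @param e_dz,e_tz,e_qz [component_energy()] at cardinals 2, 3, 4.
#' @param params a [cbs_params()].
#' @return A `cbs_result`.
#' @export
scheme2_cbs <- function(e_dz, e_tz, e_qz, params = cbs_params()) {
  stopifnot(inherits(e_dz, "component_energy"),
            inherits(e_tz, "component_energy"),
            inherits(e_qz, "component_energy"))
  corr <- two_point_power_cbs(e_tz$corr, e_qz$corr, 3, 4, 3)
  hf <- switch(params$hf_cbs_mode,
    exponential = hf_exponential_cbs(e_dz$hf, e_tz$hf, e_qz$hf),
    eq2 = two_point_power_cbs(e_dz$hf, e_tz$hf, 2, 3, params$alpha)
  )
  .new_cbs_result(hf, corr, "scheme2",
                  list(`2` = e_dz, `3` = e_tz, `4` = e_qz), params)
}

#' Extrapolate one species from an energy table
#'
#' Convenience wrapper: pulls the MP2 records a scheme needs from an
#' [energy_table()] and extrapolates.
#'
#' @param tab an [energy_table()].
#' @param complex_id,oxidation_state the species.
#' @param scheme `"scheme1"` or `"scheme2"`.
#' @param method method tag of the records to extrapolate (default `"MP2"`).
#' @param params a [cbs_params()].
#' @return A `cbs_result`.
#' @export
extrapolate_species <- function(tab, complex_id, oxidation_state,
                                scheme = c("scheme2", "scheme1"),
                                method = "MP2", params = cbs_params()) {
  scheme <- match.arg(scheme)
  grab <- function(x) lookup_energy(tab, complex_id, oxidation_state, method, x)
  if (scheme == "scheme1") {
    scheme1_cbs(grab(2), grab(3), params)
  } else {
    scheme2_cbs(grab(2), grab(3), grab(4), params)
  }
}

#' @export
print.cbs_result <- function(x, ...) {
  cat("CBS extrapolation (", x$scheme, ")\n", sep = "")
  cat("  HF   ", format(x$cbs_hf), "\n")
  cat("  corr ", format(x$cbs_corr), "\n")
  cat("  total", format(x$cbs_total), "\n")
  invisible(x)
}
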
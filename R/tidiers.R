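# broom-style tidiers for the stability analysis and GA fits.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an equilibrium analysis
#'
#' One row per eigenvalue per equilibrium, with both the closed-form
#' and numeric values where available.
#'
#' @param x An `equilibrium_analysis` from [classify_equilibria()].
#' @param ... Unused.
#' @return A tibble with columns `equilibrium`, `method`
#'   (`closed_form` / `numeric`), `real`, `imag`.
#' @export
tidy.equilibrium_analysis <- function(x, ...) {
  one <- function(r) {
    dplyr::bind_rows(
      tibble::tibble(equilibrium = r$label, method = "closed_form",
                     real = Re(r$eigenvalues_closed),
                     imag = Im(r$eigenvalues_closed)),
      tibble::tibble(equilibrium = r$label, method = "numeric",
                     real = Re(r$eigenvalues_numeric),
                     imag = Im(r$eigenvalues_numeric))
    )
  }
  dplyr::bind_rows(one(x$tumor_free), one(x$high_tumor))
}

#' One-row summary of an equilibrium analysis
#'
#' @param x An `equilibrium_analysis`.
#' @param ... Unused.
#' @return A one-row tibble: the growth-rate excess `kp2_minus_kd4`,
#'   the Routh-Hurwitz quantities, both verdicts per equilibrium, and
#'   the high-tumor carrying capacity (count and mm^3).
#' @export
glance.equilibrium_analysis <- function(x, ...) {
  p <- x$parameters
  cr <- x$high_tumor$criteria
  K <- if (p[["kp2"]] > p[["kd4"]]) (p[["kp2"]] - p[["kd4"]]) / p[["r2"]] else NA_real_
  tibble::tibble(
    kp2_minus_kd4 = cr$kp2_minus_kd4,
    a0 = cr$a0 %||% NA_real_, a1 = cr$a1 %||% NA_real_,
    a2 = cr$a2 %||% NA_real_, hurwitz = cr$hurwitz %||% NA_real_,
    tumor_free_criterion = x$tumor_free$criterion,
    tumor_free_numeric = x$tumor_free$numeric_verdict,
    high_tumor_criterion = x$high_tumor$criterion,
    high_tumor_numeric = x$high_tumor$numeric_verdict,
    carrying_capacity_cells = K,
    carrying_capacity_mm3 = K * p[["s_t"]]
  )
}

#' Tidy a GA calibration fit
#'
#' One row per free parameter: calibrated estimate, the base value used
#' for bounds, and the log10 estimate.
#'
#' @param x A `ga_fit` from [calibrate_ga()].
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `estimate`, `base`,
#'   `log10_estimate`, `rel_error` (relative to base).
#' @export
tidy.ga_fit <- function(x, ...) {
  est <- as.numeric(x$best_parameters[x$config$free])
  base <- as.numeric(x$base[x$config$free])
  tibble::tibble(
    parameter = x$config$free,
    estimate = est,
    base = base,
    log10_estimate = log10(est),
    rel_error = abs(est - base) / base
  )
}

#' One-row summary of a GA calibration fit
#'
#' @param x A `ga_fit`.
#' @param ... Unused.
#' @return A one-row tibble: best fitness, generations, population
#'   size, number of free parameters, seed.
#' @export
glance.ga_fit <- function(x, ...) {
  tibble::tibble(
    best_fitness = x$best_fitness,
    generations = x$config$generations,
    pop_size = x$config$pop_size,
    n_free = length(x$config$free),
    n_points = nrow(x$data),
    seed = x$config$seed
  )
}
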
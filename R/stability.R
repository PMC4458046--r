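# Equilibria, analytic Jacobian, closed-form spectra and Routh-Hurwitz
# classification of the linearized system.

#' Tumor-free equilibrium
#'
#' The steady state with no tumor and no vaccination: only the naive
#' compartment is occupied, at its homeostatic level `c1/kd1`.
#'
#' @param p A `model_parameters` object.
#' @return A `state_vector`.
#' @export
tumor_free_equilibrium <- function(p) {
  state_vector(t_n = p[["c1"]] / p[["kd1"]])
}

#' High-tumor equilibrium
#'
#' The steady state reached when vaccination fails to eradicate the
#' tumor: naive T cells at `c1/kd1`, MHC class I negative tumor cells
#' at the logistic carrying capacity `K = (kp2 - kd4)/r2`, everything
#' else extinct.
#'
#' @param p A `model_parameters` object.
#' @return A `state_vector`. When `kp2 <= kd4` the equilibrium is
#'   non-physical (negative tumor burden) and the call errors; use
#'   [classify_equilibria()] for a graceful report.
#' @export
high_tumor_equilibrium <- function(p) {
  if (p[["kp2"]] <= p[["kd4"]]) {
    stop("kp2 <= kd4: the high-tumor equilibrium is non-physical",
         call. = FALSE)
  }
  state_vector(t_n = p[["c1"]] / p[["kd1"]],
               c_neg = (p[["kp2"]] - p[["kd4"]]) / p[["r2"]])
}

#' Analytic 9x9 Jacobian of the continuous dynamics
#'
#' Exact partial derivatives of the model right-hand side at an
#' arbitrary state (not only equilibria). The `epsilon` offsets keep
#' every entry finite at the all-zero state.
#'
#' @param state A state vector.
#' @param p A `model_parameters` object.
#' @return A 9x9 numeric matrix with dimnames in state order.
#' @export
model_jacobian <- function(state, p) {
  y <- as.numeric(as_state_vector(state))
  t_n <- y[1]; t_e1 <- y[2]; lv <- y[3]; t_e2 <- y[4]
  cp <- y[5]; cn <- y[6]; t_e3 <- y[7]; ifng <- y[8]; tnfa <- y[9]

  vb <- p[["vol_b"]]; vln <- p[["vol_ln"]]
  st <- p[["s_t"]]; vi <- p[["v_i"]]; eps <- p[["epsilon"]]
  gam <- p[["gamma"]]; al <- p[["alpha"]]; k1 <- p[["k1"]]; k2 <- p[["k2"]]
  C <- cp + cn
  eC <- eps + C
  vol_t <- eps + st * C + vi * t_e3
  act <- lv / (lv + gam)
  chk <- al / (al + t_e1^2)
  conv <- p[["c3"]] * ifng / (k1 + ifng)

  J <- matrix(0, 9, 9, dimnames = list(.STATE_NAMES, .STATE_NAMES))

  J[1, 1] <- -p[["kd1"]] - p[["c2"]] * act
  J[1, 3] <- -p[["c2"]] * gam * t_n / (lv + gam)^2

  J[2, 1] <- p[["c2"]] * vb * lv / (vln * (lv + gam))
  J[2, 2] <- p[["kp1"]] * act * chk +
    p[["kp1"]] * t_e1 * act * (-2 * al * t_e1 / (al + t_e1^2)^2) -
    p[["a12"]]
  J[2, 3] <- p[["c2"]] * t_n * gam * vb / (vln * (lv + gam)^2) +
    p[["kp1"]] * gam * t_e1 / (lv + gam)^2 * chk
  J[2, 4] <- p[["a21"]] * vb / vln

  J[3, 3] <- -p[["kd2"]]

  J[4, 2] <- p[["a12"]] * vln / vb
  J[4, 4] <- -p[["kd3"]] - p[["a21"]] - p[["a23"]]
  J[4, 5] <- p[["a32"]] * cn * t_e3 * (eps * (st - 1) - vi * t_e3) /
    (vb * eC^2)
  J[4, 6] <- p[["a32"]] * t_e3 *
    ((eps + cp) * (eps + st * cp + 2 * st * cn + vi * t_e3) + st * cn^2) /
    (vb * eC^2)
  J[4, 7] <- p[["a32"]] * cn * (eps + st * cp + st * cn + 2 * vi * t_e3) /
    (eC * vb)

  J[5, 5] <- -p[["kp2"]] - p[["kd4"]] -
    p[["c4"]] * t_e3 * (eps + cn) / eC^2
  J[5, 6] <- conv + p[["c4"]] * t_e3 * cp / eC^2
  J[5, 7] <- -p[["c4"]] * cp / eC
  J[5, 8] <- k1 * p[["c3"]] * cn / (k1 + ifng)^2

  J[6, 5] <- 2 * p[["kp2"]]
  J[6, 6] <- -conv - p[["kd4"]] - 2 * p[["r2"]] * cn + p[["kp2"]]
  J[6, 8] <- -k1 * p[["c3"]] * cn / (k1 + ifng)^2

  J[7, 4] <- p[["a23"]] * vb / vol_t
  J[7, 5] <- -p[["a23"]] * st * t_e2 * vb / vol_t^2 +
    p[["a32"]] * t_e3 * cn / eC^2 +
    p[["kp3"]] * t_e3 * (eps + cn) / eC^2
  J[7, 6] <- -p[["a23"]] * st * t_e2 * vb / vol_t^2 -
    p[["a32"]] * t_e3 * (eps + cp) / eC^2 -
    p[["kp3"]] * t_e3 * cp / eC^2
  J[7, 7] <- -p[["a23"]] * vi * t_e2 * vb / vol_t^2 - p[["kd5"]] -
    p[["a32"]] * cn / eC + p[["kp3"]] * cp / eC

  J[8, 7] <- p[["kc1"]]
  J[8, 8] <- -p[["kd6"]]

  J[9, 7] <- p[["kc2"]] * tnfa / (k2 + tnfa) + p[["k3"]]
  J[9, 9] <- -p[["kd7"]] + p[["kc2"]] * k2 * t_e3 / (k2 + tnfa)^2

  J
}

#' Closed-form eigenvalues at the tumor-free equilibrium
#'
#' The spectrum of the Jacobian at the tumor-free equilibrium in closed
#' form: `-kd1, -kd2, -kd5, -kd6, -kd7, -(kp2 + kd4), kp2 - kd4`, plus
#' the two roots of
#' `lambda^2 + (a12 + a21 + a23 + kd3) lambda + a12 (kd3 + a23) = 0`
#' (real or complex-conjugate depending on the sign of the
#' discriminant; both always have negative real part for positive
#' parameters).
#'
#' @param p A `model_parameters` object.
#' @return Complex vector of length 9.
#' @export
eigenvalues_tumor_free <- function(p) {
  b <- p[["a12"]] + p[["a21"]] + p[["a23"]] + p[["kd3"]]
  c0 <- p[["a12"]] * (p[["kd3"]] + p[["a23"]])
  disc <- b^2 - 4 * c0
  pair <- if (disc >= 0) {
    complex(real = c(-b + sqrt(disc), -b - sqrt(disc)) / 2, imaginary = 0)
  } else {
    complex(real = -b / 2, imaginary = c(1, -1) * sqrt(-disc) / 2)
  }
  c(complex(real = c(-p[["kd1"]], -p[["kd2"]], -p[["kd5"]], -p[["kd6"]],
                     -p[["kd7"]], -(p[["kp2"]] + p[["kd4"]]),
                     p[["kp2"]] - p[["kd4"]])), pair)
}

#' Routh-Hurwitz criterion for the high-tumor equilibrium
#'
#' In the `epsilon -> 0` limit the nontrivial part of the spectrum at
#' the high-tumor equilibrium reduces to a cubic
#' `lambda^3 + a2 lambda^2 + a1 lambda + a0 = 0` with
#' `a2 = a12 + a21 + a23 + a32 + kd3 + kd5`,
#' `a1 = a12 (kd5 + a32 + kd3 + a23) + kd3 (kd5 + a32) +
#'       a21 (kd5 + a32) + kd5 a23`, and
#' `a0 = a12 (kd3 kd5 + a32 kd3 + a23 kd5)`.
#' All three coefficients are positive for positive parameters, and the
#' Routh-Hurwitz criterion (`a2 a1 - a0 > 0`) then guarantees that all
#' cubic roots lie in the open left half-plane.
#'
#' @param p A `model_parameters` object.
#' @return A list with `a0`, `a1`, `a2`, `hurwitz = a2*a1 - a0`,
#'   `roots` (the three cubic roots via [polyroot()]) and
#'   `stable_cubic` (logical verdict from the criterion).
#' @export
routh_hurwitz_high_tumor <- function(p) {
  a12 <- p[["a12"]]; a21 <- p[["a21"]]; a23 <- p[["a23"]]; a32 <- p[["a32"]]
  kd3 <- p[["kd3"]]; kd5 <- p[["kd5"]]
  a2 <- a12 + a21 + a23 + a32 + kd3 + kd5
  a1 <- a12 * (kd5 + a32 + kd3 + a23) + kd3 * (kd5 + a32) +
    a21 * (kd5 + a32) + kd5 * a23
  a0 <- a12 * (kd3 * kd5 + a32 * kd3 + a23 * kd5)
  roots <- polyroot(c(a0, a1, a2, 1))
  list(a0 = a0, a1 = a1, a2 = a2,
       hurwitz = a2 * a1 - a0,
       roots = roots,
       stable_cubic = a0 > 0 && a1 > 0 && a2 > 0 && a2 * a1 - a0 > 0)
}

#' Closed-form eigenvalues at the high-tumor equilibrium
#'
#' Spectrum in the `epsilon -> 0` limit: `-kd1, -kd2, -kd6, -kd7,
#' -(kp2 + kd4), -(kp2 - kd4)` plus the three roots of the
#' Routh-Hurwitz cubic (see [routh_hurwitz_high_tumor()]).
#'
#' @param p A `model_parameters` object.
#' @return Complex vector of length 9.
#' @export
eigenvalues_high_tumor <- function(p) {
  rh <- routh_hurwitz_high_tumor(p)
  c(complex(real = c(-p[["kd1"]], -p[["kd2"]], -p[["kd6"]], -p[["kd7"]],
                     -(p[["kp2"]] + p[["kd4"]]),
                     -(p[["kp2"]] - p[["kd4"]]))), rh$roots)
}

.max_real <- function(ev) max(Re(ev))

#' Classify the stability of both equilibria
#'
#' Runs the linearized analysis at the tumor-free and high-tumor
#' equilibria: closed-form spectra (the high-tumor closed form uses the
#' `epsilon -> 0` limit), numeric spectra of the analytic Jacobian at
#' the configured `epsilon`, the Routh-Hurwitz record, and the sign
#' criterion: for `kp2 > kd4` the tumor-free state is unstable and the
#' high-tumor state stable; for `kp2 < kd4` the verdicts swap (and the
#' high-tumor state is non-physical); `kp2 = kd4` is reported as
#' marginal, never classified.
#'
#' @param p A `model_parameters` object.
#' @return An object of class `equilibrium_analysis`: a list of two
#'   `equilibrium_report`s (`tumor_free`, `high_tumor`), each carrying
#'   the equilibrium state, closed-form and numeric eigenvalues, the
#'   criterion and numeric verdicts, and the criteria record.
#' @examples
#' fit <- classify_equilibria(default_parameters())
#' tidy(fit)
#' glance(fit)
#' @export
classify_equilibria <- function(p) {
  p <- validate_parameters(p)
  excess <- p[["kp2"]] - p[["kd4"]]
  marginal <- excess == 0
  rh <- routh_hurwitz_high_tumor(p)

  x0 <- tumor_free_equilibrium(p)
  ev0_closed <- eigenvalues_tumor_free(p)
  ev0_num <- eigen(model_jacobian(x0, p), only.values = TRUE)$values
  rep0 <- structure(list(
    label = "tumor_free",
    state = x0,
    eigenvalues_closed = ev0_closed,
    eigenvalues_numeric = ev0_num,
    criterion = if (marginal) "marginal" else
      if (excess > 0) "unstable" else "stable",
    numeric_verdict = if (.max_real(ev0_num) < 0) "stable" else
      if (.max_real(ev0_num) > 0) "unstable" else "marginal",
    criteria = list(kp2_minus_kd4 = excess)
  ), class = "equilibrium_report")

  if (excess > 0) {
    x1 <- high_tumor_equilibrium(p)
    ev1_closed <- eigenvalues_high_tumor(p)
    ev1_num <- eigen(model_jacobian(x1, p), only.values = TRUE)$values
    verdict1 <- if (rh$stable_cubic) "stable" else "unstable"
    num1 <- if (.max_real(ev1_num) < 0) "stable" else
      if (.max_real(ev1_num) > 0) "unstable" else "marginal"
    physical <- TRUE
  } else {
    x1 <- NULL
    ev1_closed <- ev1_num <- complex()
    verdict1 <- if (marginal) "marginal" else "unstable"
    num1 <- NA_character_
    physical <- FALSE
  }
  rep1 <- structure(list(
    label = "high_tumor",
    state = x1,
    physical = physical,
    eigenvalues_closed = ev1_closed,
    eigenvalues_numeric = ev1_num,
    criterion = verdict1,
    numeric_verdict = num1,
    criteria = list(kp2_minus_kd4 = excess,
                    a0 = rh$a0, a1 = rh$a1, a2 = rh$a2,
                    hurwitz = rh$hurwitz)
  ), class = "equilibrium_report")

  structure(list(tumor_free = rep0, high_tumor = rep1, parameters = p),
            class = "equilibrium_analysis")
}

#' @export
print.equilibrium_analysis <- function(x, ...) {
  cat("<equilibrium_analysis>\n")
  for (r in x[c("tumor_free", "high_tumor")]) {
    cat(sprintf("  %-11s criterion: %-9s numeric: %s\n",
                r$label, r$criterion,
                if (is.na(r$numeric_verdict %||% NA)) "n/a" else r$numeric_verdict))
  }
  invisible(x)
}

#' @importFrom rlang %||%
NULL
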
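# Continuous-time right-hand side of the nine-state model and the
# derived observables (total tumor burden, tumor-compartment volume,
# the seven measured series).

.STATE_NAMES <- c("t_n", "t_e1", "lv", "t_e2",
                  "c_pos", "c_neg", "t_e3", "ifng", "tnfa")

#' Construct a model state vector
#'
#' The nine model states, in canonical order: naive CD8+ T cells `t_n`
#' (cells mm^-3), lymph-node effectors `t_e1` (cells mm^-3),
#' adenovirus-derived antigen `lv` (RLU mm^-3), blood effectors `t_e2`
#' (cells mm^-3), MHC class I positive tumor cells `c_pos` (count),
#' MHC class I negative tumor cells `c_neg` (count), tumor effectors
#' `t_e3` (cells mm^-3), IFN-gamma `ifng` and TNF-alpha `tnfa`
#' (moles mm^-3).
#'
#' @param t_n,t_e1,lv,t_e2,c_pos,c_neg,t_e3,ifng,tnfa Non-negative
#'   state values; default 0.
#' @return Named numeric vector of length 9 (class `state_vector`).
#' @export
state_vector <- function(t_n = 0, t_e1 = 0, lv = 0, t_e2 = 0,
                         c_pos = 0, c_neg = 0, t_e3 = 0,
                         ifng = 0, tnfa = 0) {
  y <- c(t_n = t_n, t_e1 = t_e1, lv = lv, t_e2 = t_e2,
         c_pos = c_pos, c_neg = c_neg, t_e3 = t_e3,
         ifng = ifng, tnfa = tnfa)
  if (any(!is.finite(y))) stop("state values must be finite", call. = FALSE)
  if (any(y < 0)) stop("state values must be non-negative", call. = FALSE)
  structure(y, class = "state_vector")
}

as_state_vector <- function(y) {
  stopifnot(is.numeric(y), length(y) == 9L)
  if (!is.null(names(y)) && all(.STATE_NAMES %in% names(y))) {
    y <- y[.STATE_NAMES]
  } else {
    names(y) <- .STATE_NAMES
  }
  structure(as.numeric(`names<-`(y, .STATE_NAMES)),
            names = .STATE_NAMES, class = "state_vector")
}

#' Total tumor cell count
#'
#' `C(t) = c_pos + c_neg`, the total number of tumor cells regardless
#' of MHC class I status.
#'
#' @param state A state vector (or a trajectory tibble, in which case a
#'   column-wise sum is returned).
#' @return Tumor cell count (scalar or vector).
#' @export
tumor_total <- function(state) {
  if (is.data.frame(state)) return(state$c_pos + state$c_neg)
  state[["c_pos"]] + state[["c_neg"]]
}

#' Tumor compartment volume
#'
#' `Vol_t = epsilon + s_t * C(t) + v_i * t_e3` (mm^3): the small offset
#' `epsilon` plus tumor cell volume plus infiltrating effector volume.
#'
#' @param state A state vector or trajectory tibble.
#' @param p A `model_parameters` object.
#' @return Volume in mm^3.
#' @export
tumor_volume <- function(state, p) {
  te3 <- if (is.data.frame(state)) state$t_e3 else state[["t_e3"]]
  p[["epsilon"]] + p[["s_t"]] * tumor_total(state) + p[["v_i"]] * te3
}

#' Continuous-time model right-hand side
#'
#' Evaluates the time-derivative of the nine states under the
#' continuous dynamics (vaccination impulses are handled separately by
#' the integrator). The terms are, per state: saturable
#' adenovirus-driven activation of naive T cells `lv/(lv+gamma)`;
#' lymph-node effector proliferation limited by the checkpoint term
#' `alpha/(alpha + t_e1^2)`; exponential antigen decay; volume-ratio
#' scaled inter-compartment trafficking; IFN-gamma assisted conversion
#' of MHCI- to MHCI+ tumor cells; effector-mediated MHCI+ killing
#' `c4 * t_e3 * c_pos/(epsilon + C)`; logistic crowding of MHCI- cells;
#' and saturable cytokine production with first-order decay.
#'
#' @param t Time in days (the dynamics are autonomous; `t` is accepted
#'   for solver compatibility).
#' @param state Named state vector (length 9).
#' @param p A `model_parameters` object.
#' @return Named numeric vector of derivatives (length 9).
#' @export
model_rhs <- function(t, state, p) {
  y <- as.numeric(state)
  t_n <- y[1]; t_e1 <- y[2]; lv <- y[3]; t_e2 <- y[4]
  c_pos <- y[5]; c_neg <- y[6]; t_e3 <- y[7]; ifng <- y[8]; tnfa <- y[9]

  vol_b <- p[["vol_b"]]; vol_ln <- p[["vol_ln"]]
  eps <- p[["epsilon"]]
  C <- c_pos + c_neg
  vol_t <- eps + p[["s_t"]] * C + p[["v_i"]] * t_e3
  act <- lv / (lv + p[["gamma"]])               # saturable antigen drive
  chk <- p[["alpha"]] / (p[["alpha"]] + t_e1^2) # checkpoint brake
  conv <- p[["c3"]] * ifng / (p[["k1"]] + ifng) # MHCI- -> MHCI+ conversion

  d <- numeric(9)
  d[1] <- p[["c1"]] - p[["kd1"]] * t_n - p[["c2"]] * t_n * act
  d[2] <- p[["c2"]] * t_n * vol_b / vol_ln * act +
    p[["kp1"]] * t_e1 * act * chk +
    p[["a21"]] * t_e2 * vol_b / vol_ln - p[["a12"]] * t_e1
  d[3] <- -p[["kd2"]] * lv
  d[4] <- -p[["kd3"]] * t_e2 + p[["a12"]] * t_e1 * vol_ln / vol_b -
    p[["a21"]] * t_e2 +
    p[["a32"]] * c_neg / (eps + C) * t_e3 * vol_t / vol_b -
    p[["a23"]] * t_e2
  d[5] <- conv * c_neg - p[["kp2"]] * c_pos - p[["kd4"]] * c_pos -
    p[["c4"]] * t_e3 * c_pos / (eps + C)
  d[6] <- -conv * c_neg - p[["kd4"]] * c_neg + p[["kp2"]] * c_neg -
    p[["r2"]] * c_neg^2 + 2 * p[["kp2"]] * c_pos
  d[7] <- p[["a23"]] * t_e2 * vol_b / vol_t -
    p[["a32"]] * t_e3 * c_neg / (eps + C) +
    p[["kp3"]] * c_pos / (eps + C) * t_e3 - p[["kd5"]] * t_e3
  d[8] <- -p[["kd6"]] * ifng + p[["kc1"]] * t_e3
  d[9] <- -p[["kd7"]] * tnfa +
    p[["kc2"]] * tnfa / (p[["k2"]] + tnfa) * t_e3 + p[["k3"]] * t_e3

  if (any(!is.finite(d))) {
    stop("non-finite derivative at t = ", t,
         " (state or parameter pathology)", call. = FALSE)
  }
  names(d) <- .STATE_NAMES
  d
}

#' Map a model state to the seven measured observables
#'
#' Returns the observable record used by calibration: lymph-node CTL
#' (`TE1`), blood CTL (`TE2`), tumor CTL density (`TE3`, cells mm^-3,
#' reported per mg tumor under the 1 mg ~ 1 mm^3 tissue convention),
#' antigen expression (`LV`), total tumor volume (`tumor_volume`), and
#' IFN-gamma / TNF-alpha gene expression in AU (`IFNG`, `TNFA`).
#'
#' @param state A state vector or a trajectory tibble.
#' @param p A `model_parameters` object.
#' @param obs An [observation_model()].
#' @return A tibble with one row per state (columns: the seven
#'   observables).
#' @export
observe <- function(state, p, obs = observation_model()) {
  if (!is.data.frame(state)) {
    state <- tibble::as_tibble(as.list(as_state_vector(state)))
  }
  tibble::tibble(
    TE1 = state$t_e1,
    TE2 = state$t_e2,
    TE3 = state$t_e3,
    LV = state$lv,
    tumor_volume = tumor_volume(state, p),
    IFNG = obs$ifng_scale * state$ifng,
    TNFA = obs$tnfa_scale * state$tnfa
  )
}

#' Names of the seven measured observables
#' @return Character vector.
#' @export
observable_names <- function() {
  c("TE1", "TE2", "TE3", "LV", "tumor_volume", "IFNG", "TNFA")
}
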
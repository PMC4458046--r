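# Impulsive simulation: fixed-step classical RK4 between vaccination
# impulses, with the dose jump applied exactly at each scheduled time.

#' Construct a vaccination schedule
#'
#' An ordered set of impulse events `(day, dose)`: at each day the
#' adenovirus antigen state jumps by the dose,
#' `LV(t+) - LV(t-) = dose` (RLU mm^-3). Between impulses the antigen
#' decays exponentially.
#'
#' @param day Numeric vector of strictly increasing vaccination days.
#' @param dose Non-negative doses in RLU mm^-3 (recycled if scalar).
#' @return A tibble of class `vaccination_schedule` with columns `day`
#'   and `dose`.
#' @examples
#' vaccination_schedule(5, 1.1e6)                      # single shot
#' build_schedule(5, 1.1e6, 1e6, period = 5, count = 10) # + 10 boosters
#' @export
vaccination_schedule <- function(day = numeric(), dose = numeric()) {
  if (length(dose) == 1L) dose <- rep(dose, length(day))
  stopifnot(length(day) == length(dose))
  if (any(dose < 0)) stop("doses must be non-negative", call. = FALSE)
  if (is.unsorted(day, strictly = TRUE)) {
    stop("vaccination days must be strictly increasing", call. = FALSE)
  }
  structure(tibble::tibble(day = as.numeric(day), dose = as.numeric(dose)),
            class = c("vaccination_schedule", class(tibble::tibble())))
}

#' Initial model state
#'
#' Tumor inoculation at day 0: the MHC class I negative count is set to
#' the inoculum, naive CD8+ T cells to their homeostatic level (default
#' `c1/kd1`, the steady state of the naive compartment), and all other
#' states to zero.
#'
#' @param p A `model_parameters` object.
#' @param tumor_inoculum Injected tumor cell count (default 2e6).
#' @param naive_level Naive CD8+ T cell concentration in cells mm^-3
#'   (default `c1/kd1`, about 0.0714 with the calibrated values: 100
#'   naive cells distributed over a 1.4e3 mm^3 blood volume).
#' @return A `state_vector`.
#' @export
initial_state <- function(p, tumor_inoculum = 2e6,
                          naive_level = p[["c1"]] / p[["kd1"]]) {
  if (tumor_inoculum < 0) stop("tumor inoculum must be >= 0", call. = FALSE)
  state_vector(t_n = naive_level, c_neg = tumor_inoculum)
}

#' Apply a single vaccination impulse to a state
#'
#' Adds the dose to the antigen state `lv`, leaving every other
#' component unchanged.
#'
#' @param state A state vector.
#' @param dose Non-negative dose in RLU mm^-3.
#' @return The jumped state vector.
#' @export
apply_impulse <- function(state, dose) {
  if (dose < 0) stop("dose must be non-negative", call. = FALSE)
  y <- as_state_vector(state)
  y[["lv"]] <- y[["lv"]] + dose
  y
}

.params_vec <- function(p) as.numeric(validate_parameters(p))

#' Simulate the impulsive model with fixed-step RK4
#'
#' Integrates the nine-state model with the classical fourth-order
#' Runge-Kutta method on a segment-wise uniform grid that lands exactly
#' on every vaccination day; the dose jump is applied after completing
#' the step to the impulse time, and both the pre-jump and post-jump
#' states are recorded (duplicated row, `event` = -1 then +1).
#'
#' @param p A `model_parameters` object.
#' @param y0 Initial state (default [initial_state()] at the calibrated
#'   values).
#' @param schedule A [vaccination_schedule()]; events outside
#'   `[t0, t1]` are dropped with a warning.
#' @param t0,t1 Simulation window in days (default 0 to 49, the
#'   calibration horizon).
#' @param dt Maximum step in days (default 0.01; within each
#'   inter-impulse segment the actual step is the segment length
#'   divided into equal parts no longer than `dt`).
#' @param clip_negative Project negative overshoots back to zero after
#'   each step (default `TRUE`). The effector-mediated kill term is
#'   stiff when cytotoxicity is strong, and explicit stepping then
#'   oscillates the fast MHCI+ state around zero; the projection keeps
#'   the slow dynamics on track. The worst per-state excursion is
#'   recorded in the `negative_excursions` attribute either way; set
#'   `FALSE` for strict unclipped stepping.
#' @param extinction_threshold Tumor cell-count floor (default 0 =
#'   off). When positive and the total tumor count falls below it, both
#'   tumor states are absorbed at zero: counts below one cell describe
#'   a population that no longer exists, and carrying the continuum
#'   remnant forward lets it regrow unphysically. The absorbed state is
#'   an exact fixed point of the tumor sub-dynamics.
#' @return A tibble of class `ctl_trajectory` with columns `time`,
#'   `event` (0 interior, -1/+1 impulse pre/post) and the nine states;
#'   attributes record `dt`, the schedule and the parameters.
#' @examples
#' p <- default_parameters()
#' traj <- simulate_trajectory(p, schedule = vaccination_schedule(5, 1.1e6),
#'                             t1 = 20, dt = 0.05)
#' @export
simulate_trajectory <- function(p, y0 = initial_state(p),
                                schedule = vaccination_schedule(),
                                t0 = 0, t1 = 49, dt = 0.01,
                                clip_negative = TRUE,
                                extinction_threshold = 0) {
  stopifnot(t1 > t0, dt > 0)
  y0 <- as_state_vector(y0)
  keep <- schedule$day >= t0 & schedule$day <= t1
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " vaccination event(s) outside [t0, t1]")
    schedule <- schedule[keep, ]
  }
  gaps <- diff(unique(c(t0, schedule$day[schedule$day > t0], t1)))
  if (any(gaps < dt)) {
    stop("dt is larger than the smallest inter-event gap", call. = FALSE)
  }
  rows0 <- NULL
  at_t0 <- schedule$day == t0
  if (any(at_t0)) {
    pre <- y0
    y0 <- apply_impulse(y0, sum(schedule$dose[at_t0]))
    rows0 <- tibble::tibble(time = t0, event = -1L,
                            !!!as.list(as.numeric(pre) |>
                                         stats::setNames(.STATE_NAMES)))
  }
  res <- cpp_rk4_trajectory(as.numeric(y0), .params_vec(p),
                            schedule$day, schedule$dose, t0, t1, dt,
                            clip_negative, extinction_threshold)
  st <- res$state
  colnames(st) <- .STATE_NAMES
  traj <- tibble::as_tibble(as.data.frame(st))
  traj <- dplyr::bind_cols(tibble::tibble(time = res$time,
                                          event = res$event), traj)
  if (!is.null(rows0)) {
    traj$event[1] <- 1L
    traj <- dplyr::bind_rows(rows0, traj)
  }
  neg <- pmin(vapply(traj[.STATE_NAMES], min, numeric(1)),
              res$worst_negative)
  scale <- pmax(vapply(traj[.STATE_NAMES], function(x) max(abs(x)), numeric(1)),
                .Machine$double.eps)
  flagged <- .STATE_NAMES[neg < -1e-9 * scale]
  structure(traj,
            class = c("ctl_trajectory", class(tibble::tibble())),
            dt = dt, t0 = t0, t1 = t1,
            schedule = schedule, parameters = p,
            negative_excursions = stats::setNames(neg, .STATE_NAMES),
            negative_states = flagged)
}

#' @export
print.ctl_trajectory <- function(x, ...) {
  cat("<ctl_trajectory> ", nrow(x), " grid points, t in [",
      attr(x, "t0"), ", ", attr(x, "t1"), "], dt = ", attr(x, "dt"),
      ", ", nrow(attr(x, "schedule")), " impulse(s)\n", sep = "")
  neg <- attr(x, "negative_states")
  if (length(neg)) {
    cat("note: negative excursions beyond tolerance in:",
        paste(neg, collapse = ", "), "\n")
  }
  NextMethod()
}

#' Adaptive-step reference integration
#'
#' Integrates the same impulsive system segment-by-segment between
#' impulses with `deSolve::lsoda` at tight tolerances. Serves as the
#' independent cross-check for the fixed-step RK4 path.
#'
#' @inheritParams simulate_trajectory
#' @param rtol,atol Relative/absolute tolerances passed to the solver.
#' @param n_out Approximate number of output points over the whole
#'   window (the adaptive solver's internal steps are independent of
#'   this reporting grid).
#' @param maxsteps Internal step budget per solver call.
#' @param extinction_threshold Tumor cell-count floor as in
#'   [simulate_trajectory()]; implemented here with a terminal root so
#'   the absorption happens exactly at the crossing.
#' @return A `ctl_trajectory` tibble (without fixed `dt` metadata).
#' @export
simulate_reference <- function(p, y0 = initial_state(p),
                               schedule = vaccination_schedule(),
                               t0 = 0, t1 = 49,
                               rtol = 1e-10, atol = 1e-12, n_out = 200,
                               extinction_threshold = 0,
                               maxsteps = 500000) {
  y0 <- as_state_vector(y0)
  schedule <- schedule[schedule$day >= t0 & schedule$day <= t1, ]
  pv <- validate_parameters(p)
  fun <- function(t, y, parms) list(unname(model_rhs(t, y, pv)))
  rootfun <- function(t, y, parms) y[5] + y[6] - extinction_threshold
  brk <- sort(unique(c(t0, schedule$day, t1)))
  out <- list()
  y <- as.numeric(y0)
  for (s in seq_len(length(brk) - 1L)) {
    a <- brk[s]; b <- brk[s + 1L]
    kdx <- which(schedule$day == a)
    ev <- 0L
    if (length(kdx)) {
      out[[length(out) + 1L]] <- c(time = a, event = -1,
                                   stats::setNames(y, .STATE_NAMES))
      y[3] <- y[3] + sum(schedule$dose[kdx])
      ev <- 1L
    }
    first <- TRUE
    repeat {
      tseq <- seq(a, b, length.out = max(2L, ceiling(n_out * (b - a) /
                                                       (t1 - t0))))
      use_root <- extinction_threshold > 0 && y[5] + y[6] > extinction_threshold
      sol <- if (use_root) {
        deSolve::lsodar(y, tseq, fun, parms = NULL, rootfunc = rootfun,
                        rtol = rtol, atol = atol, maxsteps = maxsteps)
      } else {
        deSolve::lsoda(y, tseq, fun, parms = NULL,
                       rtol = rtol, atol = atol, maxsteps = maxsteps)
      }
      if (attr(sol, "istate")[1] < 0) {
        stop("reference solver failed on segment [", a, ", ", b, "]",
             call. = FALSE)
      }
      seg <- as.data.frame(sol)
      names(seg) <- c("time", .STATE_NAMES)
      seg$event <- c(if (first) ev else 0L, rep(0L, nrow(seg) - 1L))
      if ((s > 1L || !first) && seg$event[1] == 0L) seg <- seg[-1L, ]
      if (nrow(seg)) out[[length(out) + 1L]] <- seg
      y <- as.numeric(sol[nrow(sol), 1 + seq_len(9)])
      troot <- attr(sol, "troot")
      hit_root <- use_root && length(troot) && !is.na(troot[1]) &&
        troot[1] < b - 1e-12
      if (!hit_root) break
      # tumor extinct: absorb both tumor states at zero and continue
      y[5] <- 0; y[6] <- 0
      a <- troot[1]
      first <- FALSE
    }
  }
  traj <- dplyr::bind_rows(lapply(out, function(r) {
    if (is.data.frame(r)) r else tibble::as_tibble(as.list(r))
  }))
  traj <- dplyr::relocate(traj, "time", "event")
  structure(tibble::as_tibble(traj),
            class = c("ctl_trajectory", class(tibble::tibble())),
            dt = NA_real_, t0 = t0, t1 = t1,
            schedule = schedule, parameters = p,
            negative_excursions = stats::setNames(rep(0, 9), .STATE_NAMES),
            negative_states = character())
}

#' Final state of a trajectory
#'
#' @param traj A `ctl_trajectory`.
#' @return A `state_vector` (the last recorded, post-jump, state).
#' @export
final_state <- function(traj) {
  as_state_vector(as.numeric(traj[nrow(traj), .STATE_NAMES]))
}
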
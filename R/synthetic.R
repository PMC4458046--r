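# Synthetic observation generator emulating the calibration study
# design: seven observable series sampled on a handful of days between
# tumor inoculation (day 0) and day 49, multiplicative log-normal noise
# across replicate animals, per-point mean and SEM.

#' Default measurement design
#'
#' Emulates the sampling pattern of the calibration experiments: the
#' seven observables measured on coarse (roughly weekly, denser early
#' for the fast antigen decay) day grids within the 49-day horizon,
#' totaling 93 mean points, with a single vaccination of
#' 1.1e6 RLU mm^-3 on day 5.
#'
#' @param cv Multiplicative noise coefficient of variation per
#'   observation (default 0.2).
#' @param replicates Synthetic replicate animals per point, used for
#'   the mean and SEM (default 5).
#' @return A `measurement_design` list: `days` (named list of sampling
#'   days per observable), `cv`, `replicates`, `horizon`, `schedule`,
#'   and `n_points` (total mean points).
#' @export
default_design <- function(cv = 0.2, replicates = 5) {
  days <- list(
    TE1 = c(5, 7, 10, 14, 19, 24, 28, 33, 38, 42, 45, 47, 49),
    TE2 = c(5, 7, 10, 14, 19, 24, 28, 33, 38, 42, 45, 47, 49),
    TE3 = c(7, 10, 12, 14, 17, 19, 21, 24, 28, 33, 38, 42, 45, 49),
    LV = c(5, 6, 7, 8, 10, 12, 14, 17, 19, 21, 24, 28, 33),
    tumor_volume = c(0, 5, 7, 10, 12, 14, 17, 19, 21, 24, 26, 28, 31, 33),
    IFNG = c(7, 10, 12, 14, 17, 19, 21, 24, 28, 33, 38, 42, 45, 49),
    TNFA = c(7, 10, 12, 14, 17, 19, 21, 24, 28, 33, 38, 42)
  )
  measurement_design(days, cv = cv, replicates = replicates)
}

#' Construct a measurement design
#'
#' @param days Named list (names in [observable_names()]) of sampling
#'   days.
#' @param cv Per-observable coefficient of variation (scalar or named
#'   vector); `cv = 0` gives noiseless data with zero SEM.
#' @param replicates Replicate draws per point (>= 1).
#' @param horizon Simulation horizon in days (default 49).
#' @param schedule Vaccination protocol (default single dose 1.1e6 on
#'   day 5).
#' @return A `measurement_design` list.
#' @export
measurement_design <- function(days, cv = 0.2, replicates = 5,
                               horizon = 49,
                               schedule = vaccination_schedule(5, 1.1e6)) {
  stopifnot(is.list(days), all(names(days) %in% observable_names()),
            replicates >= 1, all(cv >= 0))
  if (length(cv) == 1L) {
    cv <- stats::setNames(rep(cv, length(days)), names(days))
  }
  stopifnot(all(names(days) %in% names(cv)))
  for (ob in names(days)) {
    d <- days[[ob]]
    if (any(d < 0 | d > horizon) || anyDuplicated(d) ||
        is.unsorted(d, strictly = TRUE)) {
      stop("sampling days for ", ob,
           " must be strictly increasing within [0, horizon]",
           call. = FALSE)
    }
  }
  structure(list(days = days, cv = cv,
                 replicates = as.integer(replicates),
                 horizon = horizon, schedule = schedule,
                 n_points = sum(lengths(days))),
            class = "measurement_design")
}

#' @export
print.measurement_design <- function(x, ...) {
  cat("<measurement_design> ", length(x$days), " observables, ",
      x$n_points, " points, horizon ", x$horizon, " days, ",
      x$replicates, " replicates\n", sep = "")
  invisible(x)
}

#' Generate a synthetic experimental dataset
#'
#' Forward-simulates the design's vaccination protocol from the given
#' parameters, samples the observables at the design days, and draws
#' `replicates` log-normal multiplicative noisy values per point
#' (median equal to the model value, coefficient of variation `cv`);
#' records their mean and SEM. Deterministic given `seed`.
#'
#' @param p A `model_parameters` object.
#' @param design A [measurement_design()].
#' @param seed Integer seed.
#' @param dt Integration step (default 0.01 day).
#' @param obs An [observation_model()].
#' @return A tidy tibble (`observable`, `day`, `value`, `sem`) valid as
#'   an experimental dataset, with the design and seed attached as
#'   attributes.
#' @examples
#' d <- generate_dataset(default_parameters(), default_design(cv = 0),
#'                       seed = 1)
#' nrow(d)  # 93 points
#' @export
generate_dataset <- function(p, design = default_design(), seed = 1L,
                             dt = 0.01, obs = observation_model()) {
  p <- validate_parameters(p)
  all_days <- sort(unique(unlist(design$days)))
  st <- cpp_rk4_sample(as.numeric(initial_state(p)), .params_vec(p),
                       design$schedule$day, design$schedule$dose,
                       0, all_days, dt, TRUE)
  colnames(st) <- .STATE_NAMES
  pred <- observe(tibble::as_tibble(as.data.frame(st)), p, obs)
  pred$day <- all_days

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(seed)

  rows <- purrr::map(names(design$days), function(ob) {
    d <- design$days[[ob]]
    mu <- pred[[ob]][match(d, pred$day)]
    cv <- design$cv[[ob]]
    sdlog <- sqrt(log1p(cv^2))
    reps <- matrix(
      if (cv > 0) {
        mu[col(matrix(0, design$replicates, length(d)))] *
          exp(stats::rnorm(design$replicates * length(d), 0, sdlog))
      } else {
        mu[col(matrix(0, design$replicates, length(d)))]
      },
      nrow = design$replicates
    )
    tibble::tibble(
      observable = ob, day = d,
      value = colMeans(reps),
      sem = if (design$replicates > 1) {
        apply(reps, 2, stats::sd) / sqrt(design$replicates)
      } else 0
    )
  })
  out <- as_experimental_dataset(dplyr::bind_rows(rows),
                                 horizon = design$horizon)
  attr(out, "design") <- design
  attr(out, "seed") <- as.integer(seed)
  out
}
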
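# Genetic-algorithm calibration: normalized squared-error plus
# normalized squared slope-difference fitness over the seven observed
# series, real-coded GA on log10-transformed parameters.

#' Validate an experimental dataset
#'
#' A calibration dataset is a tidy tibble with one row per observed
#' mean point: columns `observable` (one of [observable_names()]),
#' `day`, `value` and `sem`. The series are per-observable time
#' courses; slopes are taken between consecutive days within a series.
#'
#' @param data A data frame.
#' @param horizon Latest admissible day (default 49).
#' @return The data as a validated tibble, ordered by observable and
#'   day.
#' @export
as_experimental_dataset <- function(data, horizon = 49) {
  stopifnot(is.data.frame(data),
            all(c("observable", "day", "value") %in% names(data)))
  if (!"sem" %in% names(data)) data$sem <- NA_real_
  bad <- setdiff(unique(data$observable), observable_names())
  if (length(bad)) {
    stop("unknown observable(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(data$day < 0 | data$day > horizon)) {
    stop("observation days must lie in [0, ", horizon, "]", call. = FALSE)
  }
  if (any(data$value < 0)) stop("observed values must be >= 0", call. = FALSE)
  data <- dplyr::arrange(tibble::as_tibble(data),
                         .data$observable, .data$day)
  dup <- dplyr::summarise(dplyr::group_by(data, .data$observable),
                          dup = anyDuplicated(.data$day) > 0)
  if (any(dup$dup)) {
    stop("duplicate observation days within a series: ",
         paste(dup$observable[dup$dup], collapse = ", "), call. = FALSE)
  }
  data[c("observable", "day", "value", "sem")]
}

#' Finite-difference slopes of a time series
#'
#' Slopes `(v[i+1] - v[i]) / (d[i+1] - d[i])` between consecutive
#' observation days; the slope component of the calibration fitness
#' compares these between data and model.
#'
#' @param day Strictly increasing numeric vector (>= 2 points).
#' @param value Numeric vector of the same length.
#' @return Numeric vector of length `length(day) - 1`.
#' @export
series_slopes <- function(day, value) {
  stopifnot(length(day) == length(value), length(day) >= 2)
  if (anyDuplicated(day)) stop("duplicate days", call. = FALSE)
  if (is.unsorted(day, strictly = TRUE)) {
    stop("days must be strictly increasing", call. = FALSE)
  }
  diff(value) / diff(day)
}

#' Genetic-algorithm configuration
#'
#' @param free Character vector of parameter names to calibrate
#'   (subset of [calibrated_parameter_names()]).
#' @param lower,upper Named bounds for the free parameters (natural
#'   scale; the chromosome is log10-encoded). Default: the base value
#'   divided/multiplied by 100.
#' @param pop_size Population size (default 100).
#' @param generations Number of generations (default 150).
#' @param tournament_size Selection tournament size (default 3).
#' @param crossover_prob Per-pair blend-crossover probability
#'   (default 0.9); crossover is BLX-alpha in log space.
#' @param blx_alpha Blend expansion factor (default 0.3).
#' @param mutation_rate Per-gene Gaussian mutation probability
#'   (default 0.1).
#' @param mutation_sd Mutation standard deviation as a fraction of each
#'   gene's log-range (default 0.05).
#' @param elitism Number of elites copied unchanged (default 2).
#' @param w_sse,w_slope Fitness weights for the normalized squared
#'   error and normalized squared slope-difference terms (default 1
#'   and 1).
#' @param seed_base Include the `base` parameter values as one
#'   individual of the initial population when they fall inside the
#'   bounds (default `TRUE`; with elitism this guarantees the returned
#'   optimum is no worse than the base values). Set `FALSE` for
#'   recovery experiments where the base doubles as the ground truth.
#' @param sem_weighting If `TRUE`, residuals are additionally weighted
#'   by inverse SEM where available (off by default: the canonical
#'   fitness does not use SEM).
#' @param dt Integration step during fitness evaluation (default 0.05
#'   day; report final fits re-simulated at 0.01).
#' @param seed Integer seed recorded and used by [calibrate_ga()].
#' @return A `ga_config` list.
#' @export
ga_config <- function(free = calibrated_parameter_names(),
                      lower = NULL, upper = NULL,
                      pop_size = 100, generations = 150,
                      tournament_size = 3,
                      crossover_prob = 0.9, blx_alpha = 0.3,
                      mutation_rate = 0.1, mutation_sd = 0.05,
                      elitism = 2,
                      w_sse = 1, w_slope = 1,
                      seed_base = TRUE,
                      sem_weighting = FALSE,
                      dt = 0.05, seed = 1L) {
  stopifnot(all(free %in% calibrated_parameter_names()),
            pop_size >= 1, generations >= 1,
            w_sse >= 0, w_slope >= 0, w_sse + w_slope > 0,
            elitism >= 0, elitism <= pop_size)
  structure(list(free = free, lower = lower, upper = upper,
                 pop_size = pop_size, generations = generations,
                 tournament_size = tournament_size,
                 crossover_prob = crossover_prob, blx_alpha = blx_alpha,
                 mutation_rate = mutation_rate, mutation_sd = mutation_sd,
                 elitism = elitism, w_sse = w_sse, w_slope = w_slope,
                 seed_base = seed_base,
                 sem_weighting = sem_weighting, dt = dt,
                 seed = as.integer(seed)),
            class = "ga_config")
}

# Simulate a candidate under the calibration protocol and sample the
# observables at the dataset's days. Returns the dataset with a `model`
# column appended.
.predict_observables <- function(p, data, schedule, dt,
                                 y0 = initial_state(p),
                                 obs = observation_model()) {
  days <- sort(unique(data$day))
  st <- cpp_rk4_sample(as.numeric(as_state_vector(y0)), .params_vec(p),
                       schedule$day, schedule$dose,
                       0, days, dt, TRUE)
  colnames(st) <- .STATE_NAMES
  pred <- observe(tibble::as_tibble(as.data.frame(st)), p, obs)
  pred$day <- days
  long <- tidyr::pivot_longer(pred, -"day", names_to = "observable",
                              values_to = "model")
  dplyr::left_join(data, long, by = c("observable", "day"))
}

#' Calibration fitness of a candidate parameter set
#'
#' Simulates the calibration protocol (by default a single vaccination
#' of 1.1e6 RLU mm^-3 on day 5 after tumor inoculation), samples the
#' model observables at each observation day, and scores
#' `w_sse * sum_s sum_i ((m_i - y_i)/N_s)^2 +
#'  w_slope * sum_s sum_j ((sm_j - sy_j)/N'_s)^2`,
#' where within each series `s` the normalizer `N_s` is the maximum
#' observed value and `N'_s` the maximum absolute observed slope
#' (degenerate all-zero series fall back to 1). Lower is better; a
#' simulation blow-up returns `Inf` so the candidate is culled.
#'
#' @param p Candidate `model_parameters`.
#' @param data An experimental dataset (see
#'   [as_experimental_dataset()]).
#' @param config A [ga_config()] (supplies weights, `dt`, SEM
#'   weighting).
#' @param schedule Vaccination schedule of the calibration protocol.
#' @param y0 Initial state.
#' @return Non-negative scalar fitness.
#' @export
ga_fitness <- function(p, data, config = ga_config(),
                       schedule = vaccination_schedule(5, 1.1e6),
                       y0 = initial_state(p)) {
  data <- as_experimental_dataset(data)
  scored <- tryCatch(
    .predict_observables(p, data, schedule, config$dt, y0 = y0),
    error = function(e) NULL)
  if (is.null(scored) || anyNA(scored$model)) return(Inf)
  tot <- 0
  for (ob in unique(scored$observable)) {
    s <- scored[scored$observable == ob, ]
    ns <- max(s$value)
    if (ns <= 0) ns <- 1
    w <- rep(1, nrow(s))
    if (config$sem_weighting && !anyNA(s$sem) && all(s$sem > 0)) {
      w <- ns / s$sem  # inverse-SEM on the normalized residual scale
    }
    tot <- tot + config$w_sse * sum((w * (s$model - s$value) / ns)^2)
    if (nrow(s) >= 2 && config$w_slope > 0) {
      sy <- series_slopes(s$day, s$value)
      sm <- series_slopes(s$day, s$model)
      nps <- max(abs(sy))
      if (nps <= 0) nps <- 1
      tot <- tot + config$w_slope * sum(((sm - sy) / nps)^2)
    }
  }
  tot
}

.default_bounds <- function(base, free, lower, upper) {
  lo <- as.numeric(base[free]) / 100
  hi <- as.numeric(base[free]) * 100
  names(lo) <- names(hi) <- free
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (any(lo <= 0) || any(hi <= lo)) {
    stop("bounds must satisfy 0 < lower < upper", call. = FALSE)
  }
  list(log_lo = log10(lo), log_hi = log10(hi))
}

# Precompiled fitness closure used inside the GA loop: identical score
# to ga_fitness() but with the per-series bookkeeping hoisted out of
# the evaluation (one C++ solve + base-R arithmetic per candidate).
.make_fast_fitness <- function(data, config, schedule,
                               obs = observation_model()) {
  days <- sort(unique(data$day))
  col_of <- c(TE1 = 2L, TE2 = 4L, TE3 = 7L, LV = 3L,
              IFNG = 8L, TNFA = 9L)
  series <- lapply(split(data, data$observable), function(sd) {
    ns <- max(sd$value)
    if (ns <= 0) ns <- 1
    sl <- if (nrow(sd) >= 2) diff(sd$value) / diff(sd$day) else numeric()
    nps <- if (length(sl)) max(abs(sl)) else 1
    if (nps <= 0) nps <- 1
    list(name = sd$observable[1],
         idx = match(sd$day, days),
         ddays = diff(sd$day),
         value = sd$value, ns = ns,
         slopes = sl, nps = nps)
  })
  ev_day <- schedule$day
  ev_dose <- schedule$dose
  function(p) {
    pv <- as.numeric(p)
    y0 <- c(pv[15] / pv[1], 0, 0, 0, 0, 2e6, 0, 0, 0)
    st <- tryCatch(
      cpp_rk4_sample(y0, pv, ev_day, ev_dose, 0, days, config$dt, TRUE),
      error = function(e) NULL)
    if (is.null(st) || anyNA(st)) return(Inf)
    tot <- 0
    for (sr in series) {
      m <- if (sr$name == "tumor_volume") {
        pv[32] + pv[30] * (st[sr$idx, 5] + st[sr$idx, 6]) +
          pv[31] * st[sr$idx, 7]
      } else if (sr$name == "IFNG") {
        obs$ifng_scale * st[sr$idx, 8]
      } else if (sr$name == "TNFA") {
        obs$tnfa_scale * st[sr$idx, 9]
      } else {
        st[sr$idx, col_of[[sr$name]]]
      }
      tot <- tot + config$w_sse * sum(((m - sr$value) / sr$ns)^2)
      if (length(sr$slopes) && config$w_slope > 0) {
        sm <- diff(m) / sr$ddays
        tot <- tot + config$w_slope * sum(((sm - sr$slopes) / sr$nps)^2)
      }
    }
    tot
  }
}

#' Calibrate model parameters with a genetic algorithm
#'
#' Generational real-coded GA over log10-encoded free parameters:
#' tournament selection, BLX-alpha blend crossover in log space,
#' per-gene Gaussian mutation, and elitism (so the best-so-far fitness
#' is non-increasing). Deterministic given `config$seed`.
#'
#' @param data An experimental dataset (tidy tibble; see
#'   [as_experimental_dataset()]).
#' @param config A [ga_config()].
#' @param base Parameter set supplying the fixed (non-free) constants
#'   and the default bounds (default: packaged calibrated values).
#' @param schedule Calibration vaccination protocol (default single
#'   dose 1.1e6 RLU mm^-3 on day 5).
#' @return An object of class `ga_fit`: list with `best_parameters`
#'   (full `model_parameters`), `best_fitness`, `history` (tibble:
#'   generation, best, mean, best_so_far), `population` (final
#'   log10-encoded matrix), `config`, `data` and `schedule`. Use
#'   [tidy.ga_fit()] / [glance.ga_fit()] / [autoplot.ga_fit()].
#' @examples
#' \donttest{
#' p <- default_parameters()
#' d <- generate_dataset(p, default_design(cv = 0), seed = 1)
#' cfg <- ga_config(free = c("kd2", "kp2"), pop_size = 20,
#'                  generations = 10, seed = 1)
#' fit <- calibrate_ga(d, cfg)
#' glance(fit)
#' }
#' @export
calibrate_ga <- function(data, config = ga_config(),
                         base = default_parameters(),
                         schedule = vaccination_schedule(5, 1.1e6)) {
  data <- as_experimental_dataset(data)
  free <- config$free
  nd <- length(free)
  bounds <- .default_bounds(base, free, config$lower, config$upper)
  lo <- bounds$log_lo; hi <- bounds$log_hi
  rng <- hi - lo

  make_params <- function(chrom) {
    p <- unclass(base)
    p[free] <- 10^chrom
    validate_parameters(p)
  }
  evaluate <- if (config$sem_weighting) {
    function(chrom) ga_fitness(make_params(chrom), data, config, schedule)
  } else {
    fast_fitness <- .make_fast_fitness(data, config, schedule)
    function(chrom) fast_fitness(make_params(chrom))
  }

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  npop <- config$pop_size
  pop <- matrix(stats::runif(npop * nd, rep(lo, each = npop),
                             rep(hi, each = npop)),
                nrow = npop, ncol = nd, dimnames = list(NULL, free))
  base_chrom <- log10(as.numeric(base[free]))
  if (isTRUE(config$seed_base) &&
      all(base_chrom >= lo & base_chrom <= hi)) {
    pop[1, ] <- base_chrom
  }

  fit <- apply(pop, 1, evaluate)
  best_chrom <- pop[which.min(fit), , drop = TRUE]
  best_fit <- min(fit)
  hist <- vector("list", config$generations)

  for (g in seq_len(config$generations)) {
    ord <- order(fit)
    newpop <- matrix(NA_real_, npop, nd, dimnames = list(NULL, free))
    nelite <- min(config$elitism, npop)
    if (nelite > 0) newpop[seq_len(nelite), ] <- pop[ord[seq_len(nelite)], ]
    i <- nelite
    while (i < npop) {
      pick <- function() {
        cand <- sample.int(npop, config$tournament_size, replace = TRUE)
        pop[cand[which.min(fit[cand])], ]
      }
      p1 <- pick(); p2 <- pick()
      if (stats::runif(1) < config$crossover_prob) {
        # BLX-alpha: sample uniformly in the expanded gene-wise interval
        cmin <- pmin(p1, p2); cmax <- pmax(p1, p2)
        spread <- cmax - cmin
        c1 <- stats::runif(nd, cmin - config$blx_alpha * spread,
                           cmax + config$blx_alpha * spread)
        c2 <- stats::runif(nd, cmin - config$blx_alpha * spread,
                           cmax + config$blx_alpha * spread)
      } else {
        c1 <- p1; c2 <- p2
      }
      for (child in list(c1, c2)) {
        if (i >= npop) break
        mut <- stats::runif(nd) < config$mutation_rate
        child[mut] <- child[mut] +
          stats::rnorm(sum(mut), 0, config$mutation_sd * rng[mut])
        child <- pmin(pmax(child, lo), hi)
        i <- i + 1
        newpop[i, ] <- child
      }
    }
    pop <- newpop
    fit <- apply(pop, 1, evaluate)
    if (min(fit) < best_fit) {
      best_fit <- min(fit)
      best_chrom <- pop[which.min(fit), , drop = TRUE]
    }
    finite <- fit[is.finite(fit)]
    hist[[g]] <- tibble::tibble(generation = g,
                                best = min(fit),
                                mean = if (length(finite)) mean(finite) else Inf,
                                best_so_far = best_fit)
  }
  if (!is.finite(best_fit)) stop("no feasible candidate found", call. = FALSE)

  structure(list(
    best_parameters = make_params(best_chrom),
    best_chromosome = best_chrom,
    best_fitness = best_fit,
    history = dplyr::bind_rows(hist),
    population = pop,
    fitness = fit,
    config = config,
    data = data,
    schedule = schedule,
    base = base
  ), class = "ga_fit")
}

#' @export
print.ga_fit <- function(x, ...) {
  cat("<ga_fit> ", length(x$config$free), " free parameter(s), ",
      x$config$generations, " generations, best fitness ",
      format(x$best_fitness, digits = 6), "\n", sep = "")
  invisible(x)
}
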
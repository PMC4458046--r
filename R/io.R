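# File I/O: tidy CSVs for trajectories, datasets and schedules; JSON
# for reports and run metadata. All writers embed the seed/solver
# settings needed to reproduce the artifact.

.param_hash <- function(p) {
  # order-stable digest of the parameter values (no external digest
  # dependency: fold the bit patterns through a simple rolling hash)
  v <- sprintf("%.17g", as.numeric(p))
  h <- 0
  for (ch in utf8ToInt(paste(v, collapse = ","))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Write a trajectory to CSV with JSON metadata
#'
#' The CSV has columns `time`, `event`, the nine states and the seven
#' observables; `<path>.meta.json` records dt, horizon, schedule,
#' parameter hash and package version.
#'
#' @param traj A `ctl_trajectory`.
#' @param path Output CSV path.
#' @param obs An [observation_model()] for the observable columns.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, obs = observation_model()) {
  p <- attr(traj, "parameters")
  out <- dplyr::bind_cols(tibble::as_tibble(traj), observe(traj, p, obs))
  readr::write_csv(out, path)
  meta <- list(
    dt = attr(traj, "dt"), t0 = attr(traj, "t0"), t1 = attr(traj, "t1"),
    schedule = as.data.frame(attr(traj, "schedule")),
    parameter_hash = .param_hash(p),
    parameters = as.list(unclass(p)),
    negative_states = attr(traj, "negative_states"),
    package_version = as.character(utils::packageVersion("tcellvax"))
  )
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path CSV path.
#' @return A tibble (state and observable columns; metadata from the
#'   side-car JSON attached as attributes when present).
#' @export
read_trajectory <- function(path) {
  traj <- readr::read_csv(path, show_col_types = FALSE)
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(traj, "dt") <- meta$dt
    attr(traj, "t0") <- meta$t0
    attr(traj, "t1") <- meta$t1
    attr(traj, "schedule") <- do.call(vaccination_schedule, meta$schedule)
    attr(traj, "parameters") <- validate_parameters(unlist(meta$parameters))
  }
  traj
}

#' Write / read an experimental dataset CSV
#'
#' Tidy dialect: columns `observable`, `day`, `value`, `sem`.
#'
#' @param data A dataset tibble.
#' @param path CSV path.
#' @return `path` (writer) or the validated tibble (reader).
#' @export
write_dataset <- function(data, path) {
  readr::write_csv(as_experimental_dataset(data), path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  tryCatch(as_experimental_dataset(raw), error = function(e) {
    stop("malformed dataset '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Read a vaccination schedule from CSV or YAML
#'
#' CSV: columns `day`, `dose`. YAML: a list of `{day:, dose:}` records
#' or parallel `day:` / `dose:` sequences.
#'
#' @param path File path (`.csv`, `.yml` or `.yaml`).
#' @return A [vaccination_schedule()].
#' @export
read_schedule <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    raw <- yaml::read_yaml(path)
    if (!is.null(raw$day)) {
      vaccination_schedule(unlist(raw$day), unlist(raw$dose))
    } else {
      vaccination_schedule(vapply(raw, function(r) r$day, numeric(1)),
                           vapply(raw, function(r) r$dose, numeric(1)))
    }
  } else {
    df <- readr::read_csv(path, show_col_types = FALSE)
    vaccination_schedule(df$day, df$dose)
  }
}

#' Write a stability report
#'
#' JSON (machine-readable: equilibria, eigenvalues, criteria, verdicts)
#' plus an adjacent plain-text summary.
#'
#' @param analysis An `equilibrium_analysis`.
#' @param path Output JSON path; `<path>.txt` gets the text summary.
#' @return `path`, invisibly.
#' @export
write_stability_report <- function(analysis, path) {
  ser <- function(r) {
    list(
      label = r$label,
      state = if (is.null(r$state)) NULL else as.list(unclass(r$state)),
      physical = r$physical %||% TRUE,
      eigenvalues_closed = lapply(r$eigenvalues_closed,
                                  function(z) list(re = Re(z), im = Im(z))),
      eigenvalues_numeric = lapply(r$eigenvalues_numeric,
                                   function(z) list(re = Re(z), im = Im(z))),
      criterion = r$criterion,
      numeric_verdict = r$numeric_verdict,
      criteria = r$criteria
    )
  }
  obj <- list(
    tumor_free = ser(analysis$tumor_free),
    high_tumor = ser(analysis$high_tumor),
    parameter_hash = .param_hash(analysis$parameters),
    package_version = as.character(utils::packageVersion("tcellvax"))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  txt <- utils::capture.output({
    print(analysis)
    print(glance(analysis))
  })
  writeLines(txt, paste0(path, ".txt"))
  invisible(path)
}

#' Write a GA calibration result
#'
#' JSON with the best parameters, fitness, seed and config, plus a CSV
#' fitness history.
#'
#' @param fit A `ga_fit`.
#' @param path Output JSON path; `<path>.history.csv` gets the
#'   per-generation history.
#' @return `path`, invisibly.
#' @export
write_calibration_result <- function(fit, path) {
  obj <- list(
    best_parameters = as.list(unclass(fit$best_parameters)),
    best_fitness = fit$best_fitness,
    free = fit$config$free,
    seed = fit$config$seed,
    config = fit$config[c("pop_size", "generations", "tournament_size",
                          "crossover_prob", "blx_alpha", "mutation_rate",
                          "mutation_sd", "elitism", "w_sse", "w_slope",
                          "dt")],
    parameter_hash = .param_hash(fit$best_parameters),
    package_version = as.character(utils::packageVersion("tcellvax"))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  readr::write_csv(fit$history, paste0(path, ".history.csv"))
  invisible(path)
}
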
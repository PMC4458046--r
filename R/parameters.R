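# Model constants: 27 calibrated rate/saturation/proportionality constants
# plus fixed physical constants (compartment volumes, cell sizes, epsilon).

.CALIBRATED_NAMES <- c(
  "kd1", "kd2", "kd3", "kd4", "kd5", "kd6", "kd7",
  "kp1", "kp2", "kp3",
  "a12", "a21", "a23", "a32",
  "c1", "c2", "c3", "c4",
  "alpha", "k1", "k2", "k3", "kc1", "kc2", "gamma", "beta1", "r2"
)

.PHYSICAL_NAMES <- c("vol_b", "vol_ln", "s_t", "v_i", "epsilon")

.PARAM_NAMES <- c(.CALIBRATED_NAMES, .PHYSICAL_NAMES)

#' Construct a validated model parameter set
#'
#' Builds the full constant set of the three-compartment CD8+ T cell /
#' tumor model: 27 calibrated rate, saturation and proportionality
#' constants and 5 fixed physical constants (blood and lymph-node
#' compartment volumes, tumor and effector cell volumes, and the small
#' positive offset `epsilon` used both as a tumor-compartment volume
#' offset and as a tumor cell count offset).
#'
#' @param ... Named numeric overrides of individual constants (e.g.
#'   `c4 = 2.49e5`). Unnamed arguments are an error.
#' @param base A named list or numeric vector supplying all constants;
#'   defaults to the packaged calibrated values (see
#'   [default_parameters()]).
#'
#' @return An object of class `model_parameters`: a named numeric vector
#'   of length 32 with a validated, fixed name order.
#'
#' @details Units: rate constants in day^-1 except `c1`
#'   (cell mm^-3 day^-1), `c4` (mm^3 day^-1), `k3`, `kc1`, `kc2`
#'   (moles day^-1 cell^-1) and `r2` (cell^-1 day^-1); saturation
#'   constants `alpha` ((cell mm^-3)^2), `gamma` (RLU mm^-3), `k1`, `k2`
#'   (moles mm^-3); volumes in mm^3. The derived logistic carrying
#'   capacity is `K = (kp2 - kd4) / r2` (tumor cell count) whenever
#'   `kp2 > kd4`.
#'
#' @examples
#' p <- model_parameters()
#' carrying_capacity(p)
#' p_enhanced <- model_parameters(c4 = 2.49e5)
#' @export
model_parameters <- function(..., base = default_parameters()) {
  overrides <- c(...)
  p <- as.numeric(unlist(base)[.PARAM_NAMES])
  names(p) <- .PARAM_NAMES
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      stop("parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(overrides), .PARAM_NAMES)
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(overrides)] <- overrides
  }
  validate_parameters(p)
}

#' Packaged calibrated parameter values
#'
#' Reads the calibrated constant fixture shipped with the package.
#'
#' @return A `model_parameters` vector.
#' @export
default_parameters <- function() {
  path <- system.file("extdata", "calibrated_parameters.yaml",
                      package = "tcellvax", mustWork = TRUE)
  vals <- yaml::read_yaml(path)
  p <- as.numeric(unlist(vals)[.PARAM_NAMES])
  names(p) <- .PARAM_NAMES
  validate_parameters(p)
}

validate_parameters <- function(p) {
  stopifnot(is.numeric(p), length(p) == length(.PARAM_NAMES))
  p <- p[.PARAM_NAMES]
  if (anyNA(p)) {
    stop("missing parameter(s): ",
         paste(.PARAM_NAMES[is.na(p)], collapse = ", "), call. = FALSE)
  }
  if (any(p <= 0)) {
    stop("all model constants must be strictly positive; offending: ",
         paste(names(p)[p <= 0], collapse = ", "), call. = FALSE)
  }
  structure(p, class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters> 27 calibrated + 5 physical constants\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Derived logistic carrying capacity
#'
#' `K = (kp2 - kd4) / r2`, the asymptotic MHC class I negative tumor
#' cell count of the logistic growth term.
#'
#' @param p A `model_parameters` object.
#' @return Tumor cell count (positive when `kp2 > kd4`, otherwise the
#'   formula value is returned with a warning: the high-tumor state is
#'   then non-physical).
#' @export
carrying_capacity <- function(p) {
  K <- (p[["kp2"]] - p[["kd4"]]) / p[["r2"]]
  if (K <= 0) {
    warning("kp2 <= kd4: carrying capacity is non-positive (no high-tumor state)")
  }
  K
}

#' Names of the calibrated constants
#'
#' The 27 constants determined by calibration (as opposed to the fixed
#' physical constants), in canonical order. Useful for selecting which
#' parameters a calibration run should treat as free.
#'
#' @return Character vector of length 27.
#' @export
calibrated_parameter_names <- function() .CALIBRATED_NAMES

#' Observation model mapping states to measured series
#'
#' Scale factors mapping model states to the seven measured observables:
#' lymph-node, blood and tumor CTL concentrations, adenovirus-derived
#' antigen expression, total tumor volume, and IFN-gamma / TNF-alpha
#' gene expression in arbitrary units (AU). CTL and antigen observables
#' are the states themselves; cytokine AU are `scale * concentration`.
#'
#' @param ifng_scale,tnfa_scale Positive gene-expression AU per
#'   (moles mm^-3). Default 1.
#' @return An `observation_model` list.
#' @export
observation_model <- function(ifng_scale = 1, tnfa_scale = 1) {
  stopifnot(ifng_scale > 0, tnfa_scale > 0)
  structure(list(ifng_scale = ifng_scale, tnfa_scale = tnfa_scale),
            class = "observation_model")
}
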
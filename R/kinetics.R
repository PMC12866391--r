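#' Parametric tissue kinetics
#'
#' Voxel time courses are modelled with a Bateman-type two-exponential
#' function,
#' \deqn{u(t) = b + A\,(e^{-\lambda_{out} t} - e^{-\lambda_{in} t}),}
#' the simplest form with a single interior peak, a tunable uptake rate
#' \eqn{\lambda_{in}} and washout rate \eqn{\lambda_{out}}, and an optional
#' additive baseline \eqn{b} (for tissues with a circulating background
#' signal).  With \eqn{\lambda_{out} > 0} the peak sits at
#' \eqn{t^\ast = \log(\lambda_{in}/\lambda_{out}) /
#' (\lambda_{in}-\lambda_{out})}; with \eqn{\lambda_{out} = 0} the curve
#' rises monotonically to the plateau \eqn{b + A}.
#'
#' @param amplitude Curve scale `A` in SUV; non-negative.
#' @param lambda_in Uptake rate, 1/min; must exceed `lambda_out`.
#' @param lambda_out Washout rate, 1/min; non-negative.
#' @param baseline Additive SUV offset; default 0.
#' @param class_name Optional tissue class label carried along for
#'   bookkeeping.
#' @return A one-row tibble of class `kinetic_params`.
#' @examples
#' p <- kinetic_params(10, lambda_in = 1, lambda_out = 0.05)
#' tac_peak_time(p)  # log(20) / 0.95 ~ 3.15 min
#' @export
kinetic_params <- function(amplitude, lambda_in, lambda_out,
                           baseline = 0, class_name = NA_character_) {
  if (amplitude < 0) abort("`amplitude` must be non-negative.")
  if (lambda_out < 0) abort("`lambda_out` must be non-negative.")
  if (lambda_in <= lambda_out) {
    abort("`lambda_in` must be strictly greater than `lambda_out`.")
  }
  out <- tibble(
    class_name = class_name,
    amplitude = amplitude,
    lambda_in = lambda_in,
    lambda_out = lambda_out,
    baseline = baseline
  )
  class(out) <- c("kinetic_params", class(out))
  out
}

#' Evaluate a kinetic model at given times
#'
#' @param params A [kinetic_params()] row (or a one-row data frame with the
#'   same columns).
#' @param t_min Times post-injection in minutes; non-negative.
#' @return SUV values, same length as `t_min`.
#' @export
tac_model <- function(params, t_min) {
  if (any(t_min < 0)) abort("`t_min` must be non-negative.")
  if (params$lambda_in <= params$lambda_out) {
    abort("`lambda_in` must be strictly greater than `lambda_out`.")
  }
  params$baseline + params$amplitude *
    (exp(-params$lambda_out * t_min) - exp(-params$lambda_in * t_min))
}

#' Closed-form peak time of a kinetic model
#'
#' @inheritParams tac_model
#' @return Peak time in minutes; `Inf` when `lambda_out = 0` (the curve is
#'   monotone non-decreasing and only peaks in the limit).
#' @export
tac_peak_time <- function(params) {
  if (params$lambda_out == 0) return(Inf)
  log(params$lambda_in / params$lambda_out) /
    (params$lambda_in - params$lambda_out)
}

# Exact frame average of the model over [t0, t1] (minutes).  Using the
# analytic integral keeps frame averaging exact for constant curves and
# avoids quadrature error in the generator.
tac_frame_mean <- function(params, t0_min, t1_min) {
  dt <- t1_min - t0_min
  int_exp <- function(lam) {
    if (lam == 0) return(dt)
    (exp(-lam * t0_min) - exp(-lam * t1_min)) / lam
  }
  params$baseline + params$amplitude *
    (int_exp(params$lambda_out) - int_exp(params$lambda_in)) / dt
}

#' Default tissue kinetic classes
#'
#' The package's reference kinetic library: one Bateman parameter set per
#' tissue class, chosen so that the synthetic phantom reproduces the
#' qualitative contrasts seen in dynamic FAPI PET of the pancreas.
#' Malignant tissue accumulates slowly (late peak, ~25% washout by 60 min),
#' inflammatory lesions peak early (~5.5 min) with strong washout,
#' post-surgical reactive tissue peaks even earlier with near-complete
#' washout, kidneys, liver and blood are early-transit
#' organs (peak within the first two minutes, fast clearance), and muscle
#' and fat are near-noise background tissues.  All values are synthetic module constants, not
#' measurements.
#'
#' @return A `kinetic_params` tibble with one row per tissue class.
#' @export
tissue_kinetics <- function() {
  out <- dplyr::bind_rows(
    kinetic_params(13.7, 0.12, 0.010, 0,    "malignant"),
    kinetic_params(12.0, 0.45, 0.050, 0,    "inflammatory"),
    kinetic_params(12.0, 0.90, 0.070, 0,    "reactive"),
    kinetic_params(20.0, 6.00, 0.120, 0,    "kidney"),
    kinetic_params(3.5,  2.50, 0.120, 0.2,  "liver"),
    kinetic_params(2.5,  8.00, 0.250, 1.2,  "blood"),
    kinetic_params(0.15, 2.50, 0.150, 0.05, "muscle"),
    kinetic_params(0.08, 2.00, 0.130, 0.03, "fat")
  )
  class(out) <- c("kinetic_params", class(out))
  out
}

#' Kinetic subpopulations for intralesional heterogeneity
#'
#' Returns `n` kinetic variants of a lesion class for building lesions with
#' mixed subpopulations.  The first variant is the class default; further
#' variants step the washout rate up by the generator's default contrast (a
#' faster-clearing subclone with an earlier peak), so that subpopulations
#' are kinetically separable while remaining lesion-like.
#'
#' @param class_name Lesion class to start from (default `"malignant"`).
#' @param n Number of subpopulations (1-3).
#' @return A `kinetic_params` tibble with `n` rows.
#' @export
lesion_subpopulations <- function(class_name = "malignant", n = 2) {
  if (!n %in% 1:3) abort("`n` must be 1, 2 or 3.")
  base <- dplyr::filter(tissue_kinetics(), .data$class_name == !!class_name)
  if (nrow(base) == 0) abort(sprintf("Unknown tissue class '%s'.", class_name))
  variants <- list(
    base,
    kinetic_params(10.0, 0.22, 0.040, base$baseline, paste0(class_name, "_sub2")),
    kinetic_params(8.0,  0.35, 0.080, base$baseline, paste0(class_name, "_sub3"))
  )
  out <- dplyr::bind_rows(variants[seq_len(n)])
  class(out) <- c("kinetic_params", class(out))
  out
}
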
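#' Thresholds, cutoffs and polynomial coefficients
#'
#' The clinically anchored constants of the two estimators: od-value cutoffs
#' 32 and 42 for detecting infarcts >70 ml and >100 ml, the od-to-volume
#' polynomial `1.1*od + 0.03*od^2`, and the 70/100 ml volume thresholds.
#' The od cutoff comparison is inclusive (`>=`) by default.
#'
#' @param od_cutoff_70,od_cutoff_100 od-value cutoffs (dimensionless,
#'   `od_cutoff_70 < od_cutoff_100`).
#' @param volume_threshold_small,volume_threshold_large volume thresholds in
#'   ml defining "large" lesions.
#' @param od_poly_lin,od_poly_quad coefficients of the od-to-ml polynomial.
#' @param od_cutoff_inclusive logical; if `TRUE` (default) an od-value equal
#'   to the cutoff classifies positive.
#' @return An object of class `threshold_config`.
#' @export
threshold_config <- function(od_cutoff_70 = 32, od_cutoff_100 = 42,
                             volume_threshold_small = 70,
                             volume_threshold_large = 100,
                             od_poly_lin = 1.1, od_poly_quad = 0.03,
                             od_cutoff_inclusive = TRUE) {
  if (od_cutoff_70 <= 0 || od_cutoff_100 <= 0 || od_cutoff_70 >= od_cutoff_100)
    stop("cutoffs must be positive with od_cutoff_70 < od_cutoff_100")
  if (od_poly_lin <= 0 || od_poly_quad <= 0)
    stop("polynomial coefficients must be positive")
  structure(
    list(od_cutoff_70 = od_cutoff_70, od_cutoff_100 = od_cutoff_100,
         volume_threshold_small = volume_threshold_small,
         volume_threshold_large = volume_threshold_large,
         od_poly_lin = od_poly_lin, od_poly_quad = od_poly_quad,
         od_cutoff_inclusive = isTRUE(od_cutoff_inclusive)),
    class = "threshold_config"
  )
}

#' The od-value: product of the two orthogonal diameters
#'
#' `a * b` with both diameters in cm; dimensionless by convention, reported
#' to one decimal at presentation while full precision is kept internally.
#'
#' @param a_cm maximum lesion diameter in cm.
#' @param b_cm maximal orthogonal diameter in cm; requires `a >= b >= 0`.
#' @return The od-value (full precision).
#' @export
od_value <- function(a_cm, b_cm) {
  if (any(b_cm < 0) || any(a_cm < b_cm))
    stop("diameters must satisfy a_cm >= b_cm >= 0")
  a_cm * b_cm
}

#' Convert an od-value to a volume in ml
#'
#' The quadratic calibration `1.1*od + 0.03*od^2`, strictly increasing on
#' `od >= 0`, mapping the cutoffs 32 and 42 to 65.92 and 99.12 ml — close to
#' the 70 and 100 ml thresholds they screen for.
#'
#' @param od od-value(s), `>= 0`.
#' @param config a [threshold_config] carrying the coefficients.
#' @return Estimated volume(s) in ml.
#' @export
od_to_volume <- function(od, config = threshold_config()) {
  if (any(od < 0)) stop("od-value must be >= 0")
  config$od_poly_lin * od + config$od_poly_quad * od^2
}

#' The ABC/2 ellipsoid volume approximation
#'
#' `a * b * (n_slices * thickness) / 2`: the two in-slice orthogonal
#' diameters times the cranio-caudal extent (lesion-bearing slice count
#' times slice thickness), halved. With all lengths in cm the result is
#' directly in ml.
#'
#' @param a_cm,b_cm orthogonal diameters in cm, `a >= b >= 0`.
#' @param n_slices number of slices showing lesion, `>= 0`.
#' @param thickness_cm slice thickness in cm, `> 0`.
#' @return Estimated volume in ml.
#' @export
abc2_volume <- function(a_cm, b_cm, n_slices, thickness_cm) {
  if (any(b_cm < 0) || any(a_cm < b_cm))
    stop("diameters must satisfy a_cm >= b_cm >= 0")
  if (any(n_slices < 0)) stop("`n_slices` must be >= 0")
  if (any(thickness_cm <= 0)) stop("`thickness_cm` must be positive")
  a_cm * b_cm * n_slices * thickness_cm / 2
}

#' Classify a lesion as exceeding a volume threshold
#'
#' The od-cutoff rule calls a lesion large when its od-value reaches the
#' cutoff mapped to the threshold (32 for >70 ml, 42 for >100 ml); the
#' ABC/2 rule compares the estimated volume directly (strictly greater, as
#' the thresholds are defined as ">70 ml" / ">100 ml"). Ground-truth labels
#' use the same strict comparison on the manual volume.
#'
#' @param estimates a list or one-row data frame with fields `od_value` and
#'   `abc2_volume_ml` (e.g. a row from [run_patient()]).
#' @param config a [threshold_config].
#' @param method `"od_cutoff"` or `"abc2"`.
#' @param threshold_label `"70ml"` or `"100ml"`.
#' @return Logical: positive ("large lesion") or not.
#' @export
classify_large_lesion <- function(estimates, config = threshold_config(),
                                  method = c("od_cutoff", "abc2"),
                                  threshold_label = c("70ml", "100ml")) {
  method <- match.arg(method)
  threshold_label <- match.arg(threshold_label)
  if (method == "od_cutoff") {
    cutoff <- if (threshold_label == "70ml") config$od_cutoff_70
              else config$od_cutoff_100
    if (config$od_cutoff_inclusive) estimates$od_value >= cutoff
    else estimates$od_value > cutoff
  } else {
    thr <- if (threshold_label == "70ml") config$volume_threshold_small
           else config$volume_threshold_large
    estimates$abc2_volume_ml > thr
  }
}

#' Ground-truth large-lesion label
#'
#' @param manual_volume_ml gold-standard volume(s) in ml.
#' @param threshold_ml volume threshold in ml.
#' @return Logical: `manual_volume_ml > threshold_ml` (strict).
#' @export
truth_label <- function(manual_volume_ml, threshold_ml) {
  manual_volume_ml > threshold_ml
}
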
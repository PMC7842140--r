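#' Predicted onset time of contrast enhancement
#'
#' Onset time of first MRI contrast enhancement after irradiation, modelled
#' as affine in log dose: t_on(D) = t1 + t2 * ln(D / Gy) with t2 < 0, so
#' onset decreases logarithmically with increasing dose. Negative predicted
#' onsets (doses beyond exp(t1/|t2|)) are clamped to 0 weeks, since lesion
#' onset cannot precede irradiation.
#'
#' @param dose Dose in Gy; strictly positive (vectorised).
#' @param params A \code{\link{dvr_params}} object carrying \code{t1}, \code{t2}.
#' @return Onset time(s) in weeks after irradiation.
#' @examples
#' onset_time(80, reference_params("C3H/He"))  # ~1 week
#' @export
onset_time <- function(dose, params) {
  validate_params(params)
  if (!has_onset_params(params))
    stop("params must carry onset parameters t1 and t2", call. = FALSE)
  dose <- as.numeric(dose)
  if (any(!is.finite(dose)) || any(dose <= 0))
    stop("dose must be strictly positive and finite", call. = FALSE)
  pmax(0, params$t1 + params$t2 * log(dose))
}

#' Predicted contrast-enhancing lesion volume
#'
#' Lesion volume growth law: log10(V / ul) = a * (D - D0) * (t / week)^b.
#' Log volume grows linearly with dose above the threshold dose D0 and as a
#' power b of follow-up time. The model is meaningful only from the onset
#' time onwards; evaluating it before the predicted onset raises a warning
#' (not an error) when onset parameters are available.
#'
#' @param dose Dose in Gy.
#' @param t Follow-up time in weeks since irradiation; non-negative.
#' @param params A \code{\link{dvr_params}} with \code{a}, \code{b}, \code{D0}
#'   (and optionally \code{t1}, \code{t2} for the pre-onset warning).
#' @param warn_pre_onset Warn when \code{t} is before the predicted onset.
#' @return Volume(s) in microlitres.
#' @examples
#' predict_volume(80, 9.1, reference_params("C3H/He"))
#' @export
predict_volume <- function(dose, t, params, warn_pre_onset = TRUE) {
  validate_params(params)
  if (!has_volume_params(params))
    stop("params must carry volume parameters a, b and D0", call. = FALSE)
  dose <- as.numeric(dose); t <- as.numeric(t)
  if (any(!is.finite(t)) || any(t < 0))
    stop("follow-up time t must be non-negative and finite", call. = FALSE)
  if (warn_pre_onset && has_onset_params(params)) {
    pre <- dose > 0 & t < onset_time(pmax(dose, .Machine$double.eps), params)
    if (any(pre))
      warning("volume evaluated before the predicted onset time; ",
              "the growth law is only interpreted for t >= t_on(D)",
              call. = FALSE)
  }
  10^(params$a * (dose - params$D0) * t^params$b)
}

#' Time at which the lesion reaches a target volume
#'
#' Analytic inverse of \code{\link{predict_volume}}:
#' t = (log10(V) / (a * (D - D0)))^(1/b). Defined only for doses above the
#' threshold D0 and target volumes above 1 ul (where log10 V > 0).
#'
#' @param target_volume Target volume in microlitres, > 1.
#' @param dose Dose in Gy, > D0.
#' @param params A \code{\link{dvr_params}} with \code{a}, \code{b}, \code{D0}.
#' @return Time in weeks; round-trips with \code{predict_volume}.
#' @examples
#' time_to_volume(60, 80, reference_params("C3H/He"))
#' @export
time_to_volume <- function(target_volume, dose, params) {
  validate_params(params)
  if (!has_volume_params(params))
    stop("params must carry volume parameters a, b and D0", call. = FALSE)
  target_volume <- as.numeric(target_volume); dose <- as.numeric(dose)
  if (any(dose <= params$D0))
    stop("no solution: dose must exceed the threshold dose D0", call. = FALSE)
  if (any(target_volume <= 1))
    stop("no solution: target volume must exceed 1 ul", call. = FALSE)
  (log10(target_volume) / (params$a * (dose - params$D0)))^(1 / params$b)
}
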
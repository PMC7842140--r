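#' Coefficient of determination
#'
#' R^2 = 1 - SSres/SStot with SStot taken about the mean of the observed
#' values. Used on the onset-week scale for onset fits and on the
#' log10-volume scale for volume fits.
#'
#' @param observed Numeric vector of observations.
#' @param predicted Numeric vector of model predictions, same length.
#' @return R^2 (at most 1; can be negative for predictions worse than the
#'   observed mean).
#' @export
r_squared <- function(observed, predicted) {
  observed <- as.numeric(observed); predicted <- as.numeric(predicted)
  if (length(observed) == 0L || length(observed) != length(predicted))
    stop("observed and predicted must be non-empty and of equal length",
         call. = FALSE)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0)
    stop("R^2 undefined: observed values have zero variance", call. = FALSE)
  1 - sum((observed - predicted)^2) / ss_tot
}

new_dvr_fit <- function(params, free, observed, predicted, scale,
                        converged = TRUE) {
  structure(list(
    params = params,
    free = free,
    r_squared = r_squared(observed, predicted),
    n_points = length(observed),
    residuals = observed - predicted,
    fitted = predicted,
    observed = observed,
    scale = scale,
    converged = converged
  ), class = "dvr_fit")
}

#' @export
print.dvr_fit <- function(x, ...) {
  cat(sprintf("Dose-volume response fit (%s scale)\n", x$scale))
  cat("  free parameters:", paste(x$free, collapse = ", "), "\n")
  est <- unlist(x$params[x$free])
  cat("  estimates:", paste(sprintf("%s = %.6g", names(est), est),
                            collapse = ", "), "\n")
  cat(sprintf("  R^2 = %.4f on %d points\n", x$r_squared, x$n_points))
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

check_onset_frame <- function(observations) {
  observations <- as.data.frame(observations)
  req <- c("dose", "onset_week")
  if (!all(req %in% names(observations)))
    stop("observations need columns 'dose' and 'onset_week'", call. = FALSE)
  if (any(observations$dose <= 0))
    stop("onset observations require positive dose", call. = FALSE)
  if (any(observations$onset_week < 0))
    stop("onset weeks must be non-negative", call. = FALSE)
  observations
}

#' Fit the onset-time model by ordinary least squares
#'
#' Closed-form OLS regression of observed onset week on ln(dose), estimating
#' the onset intercept t1 and slope t2 of the model
#' t_on(D) = t1 + t2 ln(D/Gy). One observation per animal; unweighted.
#'
#' @param observations Data frame with columns \code{dose} (Gy) and
#'   \code{onset_week} (weeks); optionally \code{mouse_id}.
#' @return A \code{dvr_fit} whose params carry only \code{t1}, \code{t2};
#'   R^2 on the onset-week scale.
#' @examples
#' obs <- data.frame(dose = c(40, 60, 80), onset_week = c(9.6, 4.6, 1.0))
#' fit_onset_model(obs)
#' @export
fit_onset_model <- function(observations) {
  observations <- check_onset_frame(observations)
  if (nrow(observations) < 3L)
    stop("need at least 3 onset observations", call. = FALSE)
  if (length(unique(observations$dose)) < 2L)
    stop("singular design: need at least 2 distinct dose levels",
         call. = FALSE)
  fit <- stats::lm(onset_week ~ log(dose), data = observations)
  cf <- stats::coef(fit)
  if (cf[[2]] >= 0)
    warning("fitted onset slope is non-negative: onsets do not decrease ",
            "with dose in these data; slope clamped to just below zero",
            call. = FALSE)
  params <- dvr_params(t1 = cf[[1]], t2 = min(cf[[2]], -.Machine$double.eps))
  new_dvr_fit(params, free = c("t1", "t2"),
              observed = observations$onset_week,
              predicted = as.numeric(stats::fitted(fit)),
              scale = "weeks")
}

#' Validate a fitted onset model on an independent cohort
#'
#' Applies given onset parameters to a validation set without refitting.
#' R^2 = 1 - SSres/SStot where SStot uses the validation set's own mean
#' (standard out-of-sample definition).
#'
#' @param params A \code{\link{dvr_params}} carrying \code{t1}, \code{t2}.
#' @param observations Validation observations (as in
#'   \code{\link{fit_onset_model}}).
#' @return A \code{dvr_fit} with no free parameters.
#' @export
validate_onset_model <- function(params, observations) {
  validate_params(params)
  if (!has_onset_params(params))
    stop("params must carry onset parameters t1 and t2", call. = FALSE)
  observations <- check_onset_frame(observations)
  if (nrow(observations) == 0L)
    stop("empty validation set", call. = FALSE)
  pred <- onset_time(observations$dose, params)
  new_dvr_fit(params, free = character(0),
              observed = observations$onset_week, predicted = pred,
              scale = "weeks")
}

check_volume_frame <- function(points) {
  points <- as.data.frame(points)
  req <- c("dose", "t", "volume")
  if (!all(req %in% names(points)))
    stop("volume points need columns 'dose', 't' and 'volume'", call. = FALSE)
  if (any(points$volume <= 0))
    stop("volume points must have strictly positive volume", call. = FALSE)
  if (any(points$t < 0))
    stop("volume points must have non-negative follow-up time", call. = FALSE)
  points
}

#' Fit the volume growth model by bounded nonlinear least squares
#'
#' Globally fits log10(V/ul) = a (D - D0) t^b to pooled post-onset volume
#' points of a cohort, minimizing the residual sum of squares on the log10
#' scale over the requested free parameters with the remaining ones held
#' fixed. With only a few dose levels a and D0 are weakly identified, so the
#' fit uses a single deterministic start (a = 0.01, b = 0.5,
#' D0 = min dose - 10 Gy) and box bounds a in (0, 1], b in (0, 2],
#' D0 in [0, min dose). The cross-strain transfer fit is this operation with
#' \code{free = "b"} and a, D0 fixed at their training-cohort estimates.
#'
#' @param points Data frame with columns \code{dose} (Gy), \code{t} (weeks)
#'   and \code{volume} (ul, positive); optionally \code{mouse_id}.
#' @param free Character subset of \code{c("a", "b", "D0")} to estimate.
#' @param fixed A \code{\link{dvr_params}} supplying values for the
#'   non-free parameters (ignored entries may be \code{NA}).
#' @param init Optional named list overriding the default starting values.
#' @return A \code{dvr_fit}; residuals and R^2 on the log10-volume scale.
#'   Optimizer non-convergence is flagged via \code{converged = FALSE} with
#'   a warning, never silently.
#' @examples
#' p <- reference_params("C3H/He")
#' pts <- expand.grid(dose = c(40, 60, 80), t = c(2, 6, 10, 14))
#' pts$volume <- predict_volume(pts$dose, pts$t, p, warn_pre_onset = FALSE)
#' fit_volume_model(pts)
#' @export
fit_volume_model <- function(points, free = c("a", "b", "D0"),
                             fixed = dvr_params(), init = NULL) {
  points <- check_volume_frame(points)
  if (length(free) < 1L) stop("need at least one free parameter", call. = FALSE)
  free <- match.arg(free, c("a", "b", "D0"), several.ok = TRUE)
  if (nrow(points) < length(free))
    stop("fewer points than free parameters", call. = FALSE)
  validate_params(fixed)
  for (nm in setdiff(c("a", "b", "D0"), free))
    if (is.na(fixed[[nm]]))
      stop("fixed value required for non-free parameter '", nm, "'",
           call. = FALSE)

  dmin <- min(points$dose)
  start <- list(a = 0.01, b = 0.5, D0 = max(0, dmin - 10))
  for (nm in names(init)) start[[nm]] <- init[[nm]]
  lower <- c(a = 1e-8, b = 1e-8, D0 = 0)
  upper <- c(a = 1, b = 2, D0 = dmin * (1 - 1e-9))

  ylog <- log10(points$volume)
  value_of <- function(par) {
    full <- list(
      a = if ("a" %in% free) par[["a"]] else fixed$a,
      b = if ("b" %in% free) par[["b"]] else fixed$b,
      D0 = if ("D0" %in% free) par[["D0"]] else fixed$D0
    )
    full$a * (points$dose - full$D0) * points$t^full$b
  }

  par0 <- unlist(start[free])
  res <- minpack.lm::nls.lm(
    par = par0,
    lower = lower[free], upper = upper[free],
    fn = function(par) ylog - value_of(par),
    control = minpack.lm::nls.lm.control(
      ftol = 1e-10, ptol = 1e-12, maxiter = 500))

  converged <- res$info %in% 1:4
  if (!converged)
    warning("volume-model fit did not converge: ", res$message, call. = FALSE)

  est <- res$par
  params <- dvr_params(
    a = if ("a" %in% free) est[["a"]] else fixed$a,
    b = if ("b" %in% free) est[["b"]] else fixed$b,
    D0 = if ("D0" %in% free) est[["D0"]] else fixed$D0,
    t1 = fixed$t1, t2 = fixed$t2, strain = fixed$strain)
  new_dvr_fit(params, free = free, observed = ylog,
              predicted = value_of(est), scale = "log10 volume",
              converged = converged)
}
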
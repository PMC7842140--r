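#' Dose-volume response model parameters
#'
#' Container for the five parameters of the dose-volume response model for
#' radiation-induced contrast-enhancing (CE) brain lesions:
#' \describe{
#'   \item{a}{growth-rate coefficient per Gy (1/Gy); scales how fast
#'     log10 lesion volume grows with dose above threshold.}
#'   \item{b}{time exponent (dimensionless); power of follow-up time in the
#'     log-volume growth law. Smaller \code{b} means slower progression.}
#'   \item{D0}{threshold dose (Gy) below which no CE volume growth is
#'     predicted.}
#'   \item{t1}{onset intercept (weeks): predicted onset time at 1 Gy.}
#'   \item{t2}{onset slope (weeks per ln Gy); negative, so onset time
#'     decreases with increasing dose.}
#' }
#' Any parameter may be left \code{NA} when a partial set is needed (e.g. an
#' onset-only fit carries just \code{t1}, \code{t2}).
#'
#' @param a Growth-rate coefficient (1/Gy), positive.
#' @param b Time exponent, positive.
#' @param D0 Threshold dose (Gy), non-negative.
#' @param t1 Onset intercept (weeks).
#' @param t2 Onset slope (weeks); must be negative.
#' @param strain Free-text strain label.
#'
#' @return An object of class \code{dvr_params}.
#' @examples
#' dvr_params(a = 0.0155, b = 0.40, D0 = 30, t1 = 55.75, t2 = -12.5)
#' @export
dvr_params <- function(a = NA_real_, b = NA_real_, D0 = NA_real_,
                       t1 = NA_real_, t2 = NA_real_, strain = "") {
  p <- list(a = as.numeric(a), b = as.numeric(b), D0 = as.numeric(D0),
            t1 = as.numeric(t1), t2 = as.numeric(t2),
            strain = as.character(strain))
  class(p) <- "dvr_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "dvr_params"))
  if (!is.na(p$a) && p$a <= 0) stop("'a' must be positive", call. = FALSE)
  if (!is.na(p$b) && p$b <= 0) stop("'b' must be positive", call. = FALSE)
  if (!is.na(p$D0) && p$D0 < 0) stop("'D0' must be non-negative", call. = FALSE)
  if (!is.na(p$t2) && p$t2 >= 0)
    stop("'t2' must be negative: onset time must decrease with dose",
         call. = FALSE)
  invisible(p)
}

has_onset_params <- function(p) !is.na(p$t1) && !is.na(p$t2)
has_volume_params <- function(p) !is.na(p$a) && !is.na(p$b) && !is.na(p$D0)

#' @export
print.dvr_params <- function(x, ...) {
  cat("Dose-volume response parameters",
      if (nzchar(x$strain)) paste0("[", x$strain, "]"), "\n")
  cat(sprintf("  a  = %s 1/Gy\n  b  = %s\n  D0 = %s Gy\n  t1 = %s weeks\n  t2 = %s weeks\n",
              format(x$a), format(x$b), format(x$D0),
              format(x$t1), format(x$t2)))
  invisible(x)
}

#' Reference parameter sets for the two study strains
#'
#' Returns the fitted reference parameterisation of the dose-volume response
#' model for the radiosensitive strain C3H/He (b = 0.40) or the
#' radioresistant strain C57BL/6 (b = 0.28). Both strains share
#' a = 0.0155 1/Gy, D0 = 30 Gy, t1 = 55.75 weeks and t2 = -12.5 weeks.
#'
#' @param strain One of \code{"C3H/He"} or \code{"C57BL/6"}.
#' @return A \code{\link{dvr_params}} object.
#' @examples
#' reference_params("C3H/He")
#' @export
reference_params <- function(strain = c("C3H/He", "C57BL/6")) {
  strain <- match.arg(strain)
  b <- if (strain == "C3H/He") 0.40 else 0.28
  dvr_params(a = 0.0155, b = b, D0 = 30, t1 = 55.75, t2 = -12.5,
             strain = strain)
}
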
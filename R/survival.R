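check_survival_frame <- function(records) {
  records <- as.data.frame(records)
  tcol <- if ("time" %in% names(records)) "time" else "last_week"
  if (!tcol %in% names(records) || !"event" %in% names(records))
    stop("survival records need columns 'time' (or 'last_week') and 'event'",
         call. = FALSE)
  if (any(records[[tcol]] <= 0))
    stop("survival times must be positive", call. = FALSE)
  if (!all(records$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (death/sacrifice)", call. = FALSE)
  records$time <- records[[tcol]]
  records
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survivor function from right-censored
#' follow-up times (weeks). Censored animals leave the risk set without
#' contributing an event; at tied times, censoring is counted after the
#' events (standard convention).
#'
#' @param records Data frame with columns \code{time} (or \code{last_week},
#'   weeks > 0) and \code{event} (1 = death/sacrifice, 0 = censored).
#' @return Data frame with one row per distinct observed time:
#'   \code{time}, \code{n_risk}, \code{n_event}, \code{n_censor},
#'   \code{survival}; prefixed with the S(0) = 1 row.
#' @examples
#' km_curve(data.frame(time = c(2, 4), event = c(1, 1)))
#' @export
km_curve <- function(records) {
  records <- check_survival_frame(records)
  if (nrow(records) == 0L) stop("empty survival record set", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  out <- data.frame(time = c(0, sf$time),
                    n_risk = c(sf$n, sf$n.risk),
                    n_event = c(0, sf$n.event),
                    n_censor = c(0, sf$n.censor),
                    survival = c(1, sf$surv))
  rownames(out) <- NULL
  out
}

#' Two-sample log-rank test
#'
#' Mantel-Haenszel log-rank comparison of two censored survival
#' distributions, with hypergeometric variance and joint handling of tied
#' event times; the statistic is chi-square distributed on 1 df under the
#' null of equal survival.
#'
#' @param group_a,group_b Survival record data frames (see
#'   \code{\link{km_curve}}).
#' @return List with \code{chi_square}, \code{p_value}, \code{df = 1} and
#'   the per-group observed/expected event counts.
#' @examples
#' a <- data.frame(time = c(1, 2, 3), event = 1)
#' b <- data.frame(time = c(10, 11, 12), event = 1)
#' logrank_test(a, b)
#' @export
logrank_test <- function(group_a, group_b) {
  group_a <- check_survival_frame(group_a)
  group_b <- check_survival_frame(group_b)
  if (nrow(group_a) == 0L || nrow(group_b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  if (sum(group_a$event) + sum(group_b$event) == 0)
    stop("log-rank statistic undefined: no events in either group",
         call. = FALSE)
  dat <- rbind(data.frame(time = group_a$time, event = group_a$event,
                          group = "A"),
               data.frame(time = group_b$time, event = group_b$event,
                          group = "B"))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = dat,
                           rho = 0)
  list(chi_square = as.numeric(sd$chisq),
       p_value = stats::pchisq(as.numeric(sd$chisq), df = 1,
                               lower.tail = FALSE),
       df = 1L,
       observed = as.numeric(sd$obs),
       expected = as.numeric(sd$exp))
}
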
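COHORT_HEADER <- c("mouse_id", "strain", "dose_gy", "scan_week",
                   "ce_volume_ul")
SURVIVAL_HEADER <- c("mouse_id", "strain", "dose_gy", "last_week", "event")

read_checked_csv <- function(path, header) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = NA, check.names = FALSE)
  if (!identical(names(tab), header))
    stop("malformed header in ", path, ": expected '",
         paste(header, collapse = ","), "', got '",
         paste(names(tab), collapse = ","), "'", call. = FALSE)
  tab
}

bad_rows <- function(cond) which(cond) + 1L  # +1: header line is row 1

#' Read and validate a long-format cohort scan table
#'
#' The cohort CSV has the exact header
#' \code{mouse_id,strain,dose_gy,scan_week,ce_volume_ul}: one row per MRI
#' scan with the contoured CE volume in microlitres (0 = no enhancement).
#' Malformed content is rejected with messages naming the offending file
#' rows.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_cohort <- function(path) {
  tab <- read_checked_csv(path, COHORT_HEADER)
  for (col in c("dose_gy", "scan_week", "ce_volume_ul")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v))
      stop("non-numeric '", col, "' in ", path, " at row(s) ",
           paste(bad_rows(is.na(v)), collapse = ", "), call. = FALSE)
    tab[[col]] <- v
  }
  if (any(tab$ce_volume_ul < 0))
    stop("negative CE volume in ", path, " at row(s) ",
         paste(bad_rows(tab$ce_volume_ul < 0), collapse = ", "),
         call. = FALSE)
  key <- paste(tab$mouse_id, tab$scan_week, sep = "@")
  if (anyDuplicated(key))
    stop("duplicate (mouse_id, scan_week) key '",
         key[anyDuplicated(key)], "' in ", path, " at row ",
         bad_rows(duplicated(key))[1], call. = FALSE)
  per_mouse_dose <- tapply(tab$dose_gy, tab$mouse_id,
                           function(d) length(unique(d)))
  if (any(per_mouse_dose > 1))
    stop("dose must be constant per mouse; violated for: ",
         paste(names(per_mouse_dose)[per_mouse_dose > 1], collapse = ", "),
         call. = FALSE)
  tab
}

#' Write a cohort scan table
#'
#' Comma-separated UTF-8 with mandatory header and '.' decimal; volumes
#' serialized with 6 significant digits.
#'
#' @param table Cohort data frame (columns as in \code{\link{read_cohort}}).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_cohort <- function(table, path) {
  table <- as.data.frame(table)[COHORT_HEADER]
  table$ce_volume_ul <- signif(table$ce_volume_ul, 6)
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a per-animal survival table
#'
#' Header: \code{mouse_id,strain,dose_gy,last_week,event}.
#'
#' @param path CSV file path.
#' @return Validated data frame.
#' @export
read_survival <- function(path) {
  tab <- read_checked_csv(path, SURVIVAL_HEADER)
  for (col in c("dose_gy", "last_week", "event")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(v))
      stop("non-numeric '", col, "' in ", path, " at row(s) ",
           paste(bad_rows(is.na(v)), collapse = ", "), call. = FALSE)
    tab[[col]] <- v
  }
  if (anyDuplicated(tab$mouse_id))
    stop("duplicate mouse_id in ", path, " at row ",
         bad_rows(duplicated(tab$mouse_id))[1], call. = FALSE)
  if (!all(tab$event %in% c(0, 1)))
    stop("event must be 0 or 1 in ", path, " at row(s) ",
         paste(bad_rows(!tab$event %in% c(0, 1)), collapse = ", "),
         call. = FALSE)
  tab
}

#' @rdname read_survival
#' @param table Survival data frame.
#' @export
write_survival <- function(table, path) {
  table <- as.data.frame(table)[SURVIVAL_HEADER]
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize / restore a simulation configuration as JSON
#'
#' @param config A \code{\link{sim_config}}.
#' @param path JSON file path.
#' @return \code{write_sim_config}: the path, invisibly;
#'   \code{read_sim_config}: a \code{dvr_sim_config}.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "dvr_sim_config"))
  x <- unclass(config)
  x$strains <- lapply(x$strains, function(sp) {
    list(strain = sp$strain,
         params = sp$params[c("a", "b", "D0", "t1", "t2")],
         doses = sp$doses, n_per_dose = sp$n_per_dose,
         n_control = sp$n_control)
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  strains <- lapply(x$strains, function(sp) {
    strain_spec(sp$strain,
                do.call(dvr_params,
                        c(sp$params, list(strain = sp$strain))),
                doses = unlist(sp$doses),
                n_per_dose = sp$n_per_dose, n_control = sp$n_control)
  })
  sim_config(strains = strains,
             first_scan_weeks = unlist(x$first_scan_weeks),
             biweekly_interval = x$biweekly_interval,
             late_interval = x$late_interval,
             late_start = x$late_start,
             max_followup = x$max_followup,
             sigma_log10 = x$sigma_log10,
             detection_threshold = x$detection_threshold,
             sacrifice_threshold = x$sacrifice_threshold,
             brain_volume_cap = x$brain_volume_cap,
             seed = x$seed)
}

#' Serialize a fit result to JSON
#'
#' @param fit A \code{dvr_fit}.
#' @param path JSON file path.
#' @return The path, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "dvr_fit"))
  x <- list(strain = fit$params$strain,
            params = fit$params[c("a", "b", "D0", "t1", "t2")],
            free = as.list(fit$free),
            r_squared = fit$r_squared,
            n_points = fit$n_points,
            converged = fit$converged)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}

#' Restore model parameters from a fit JSON
#'
#' @param path JSON file written by \code{\link{write_fit}}.
#' @return A \code{\link{dvr_params}}.
#' @export
read_fit_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pr <- lapply(x$params, function(v) if (is.null(v)) NA_real_ else v)
  dvr_params(a = pr$a, b = pr$b, D0 = pr$D0, t1 = pr$t1, t2 = pr$t2,
             strain = if (is.null(x$strain)) "" else x$strain)
}

# FNV-1a hash of a serialized config; recorded in run logs so an artifact
# can be traced back to the exact configuration that produced it.
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(unclass(config))),
             collapse = "\n")
  h <- 5381
  for (k in utf8ToInt(s)) h <- (h * 33 + k) %% 2147483647
  sprintf("%08x", as.integer(h))
}

log_artifact <- function(out_dir, what, config = NULL, seed = NA) {
  line <- sprintf("[%s] %s | seed=%s | config=%s | dvrmodel %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), what,
                  as.character(seed),
                  if (is.null(config)) "-" else config_hash(config),
                  as.character(utils::packageVersion("dvrmodel")))
  cat(line, "\n", file = file.path(out_dir, "run.log"), append = TRUE)
}
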
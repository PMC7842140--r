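#' Import an externally contoured CE volume table
#'
#' Adapter for longitudinal lesion-volume tables produced outside the
#' package (e.g. contoured MRI volumes exported from an imaging toolkit).
#' The file must be a CSV; columns are renamed via \code{mapping} into the
#' package's cohort schema (\code{mouse_id}, \code{strain}, \code{dose_gy},
#' \code{scan_week}, \code{ce_volume_ul}) and then validated exactly like
#' \code{\link{read_cohort}}. Centralising the mapping in one function
#' means an unknown external format only ever has to be described once.
#'
#' @param path CSV file path.
#' @param mapping Named character vector: names are the external column
#'   names, values the cohort-schema names they map to. \code{NULL} means
#'   the file already uses the cohort schema.
#' @return A validated cohort data frame.
#' @export
import_contoured_volumes <- function(path, mapping = NULL) {
  if (is.null(mapping)) return(read_cohort(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(names(mapping), names(raw))
  if (length(missing_cols))
    stop("columns not found in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  names(raw)[match(names(mapping), names(raw))] <- unname(mapping)
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(raw[COHORT_HEADER], tmp, row.names = FALSE, quote = FALSE)
  read_cohort(tmp)
}
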
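# Tumor-load measurement series: the clinical data type the model is
# calibrated against (total lesion volume over time, with optional
# per-point measurement error).

#' Construct a tumor-load series
#'
#' @param week measurement times (weeks from treatment start), increasing.
#' @param load_cm3 total lesion volume (cm^3), non-negative.
#' @param err_cm3 optional per-point measurement error (cm^3).
#' @return a data.frame of class `icisim_series`.
#' @export
tumor_load_series <- function(week, load_cm3, err_cm3 = NULL) {
  if (length(week) != length(load_cm3))
    stop("'week' and 'load_cm3' must have the same length")
  if (length(week) == 0L) stop("series must contain at least one point")
  if (any(!is.finite(week)) || any(!is.finite(load_cm3)))
    stop("series values must be finite")
  if (is.unsorted(week, strictly = TRUE)) {
    bad <- which(diff(week) <= 0)[1] + 1L
    stop("weeks must be strictly increasing; offending row ", bad)
  }
  if (any(load_cm3 < 0)) stop("tumor loads must be non-negative")
  out <- data.frame(week = as.numeric(week), load_cm3 = as.numeric(load_cm3))
  if (!is.null(err_cm3)) {
    if (length(err_cm3) != length(week))
      stop("'err_cm3' must match the number of measurements")
    out$err_cm3 <- as.numeric(err_cm3)
  }
  class(out) <- c("icisim_series", "data.frame")
  out
}

#' Read a tumor-load series from CSV
#'
#' Expects columns `week` and `load_cm3` (and optionally `err_cm3`);
#' round-trips losslessly with [save_series()].
#'
#' @param path CSV file path.
#' @return an `icisim_series`.
#' @export
load_series <- function(path) {
  if (!file.exists(path)) stop("series file not found: ", path)
  df <- tryCatch(read.csv(path), error = function(e)
    stop("cannot parse '", path, "': ", conditionMessage(e)))
  need <- c("week", "load_cm3")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("series file is missing column(s): ", paste(miss, collapse = ", "))
  tumor_load_series(df$week, df$load_cm3,
                    if ("err_cm3" %in% names(df)) df$err_cm3)
}

#' Write a tumor-load series to CSV
#' @param series an `icisim_series`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_series <- function(series, path) {
  stopifnot(inherits(series, "icisim_series"))
  write.csv(as.data.frame(series), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.icisim_series <- function(x, ...) {
  cat(sprintf("Tumor-load series: %d measurements, weeks %g-%g, load %g-%g cm^3\n",
              nrow(x), min(x$week), max(x$week), min(x$load_cm3),
              max(x$load_cm3)))
  NextMethod()
}
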
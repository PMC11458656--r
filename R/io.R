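#' Read and write NONMEM-style PK datasets
#'
#' Datasets are rectangular delimited text with one row per dose or
#' observation event and the columns `id`, `time` (h), `amt` (mg MMF, dose
#' rows), `dv` (mg/L MPA, observation rows), `evid` (1 dose, 0
#' observation), `mdv` (1 missing DV), `occ` (occasion), plus the
#' covariates `weight` (kg), `height` (cm) and `albumin` (g/L).  Column
#' names are matched case-insensitively and common NONMEM aliases (`wt`,
#' `ht`, `alb`) are accepted; extra columns are preserved.  A `.` denotes
#' a missing value.  Files are comma-delimited; tabs are accepted on read.
#'
#' Validation on read: mandatory columns present; times non-negative and
#' non-decreasing within subject; dose rows have `amt` > 0 and no DV;
#' observation rows have `evid` 0.  Violations raise errors naming the
#' offending rows.
#'
#' @param path File path.
#' @return `read_dataset()`: a validated tibble.  `write_dataset()`:
#'   `path`, invisibly.
#' @examples
#' ds <- simulate_dataset(generate_population(2, seed = 1), regimen(500),
#'                        sampling_design("limited"), seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_dataset(ds, f)
#' read_dataset(f)
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, na = c(".", "", "NA"),
                           show_col_types = FALSE, trim_ws = TRUE)
  names(raw) <- canonical_names(names(raw))
  validate_dataset(raw)
}

#' @rdname read_dataset
#' @param data A dataset tibble.
#' @export
write_dataset <- function(data, path) {
  data <- as_tibble(data)
  readr::write_csv(data, path, na = ".")
  invisible(path)
}

canonical_names <- function(nms) {
  low <- tolower(nms)
  alias <- c(wt = "weight", ht = "height", alb = "albumin", bw = "weight")
  hit <- low %in% names(alias)
  low[hit] <- alias[low[hit]]
  low
}

validate_dataset <- function(data) {
  data <- as_tibble(data)
  names(data) <- canonical_names(names(data))
  mandatory <- c("id", "time", "amt", "dv", "evid", "mdv")
  missing_cols <- setdiff(mandatory, names(data))
  if (length(missing_cols) > 0) {
    abort(paste("dataset is missing mandatory column(s):",
                paste(missing_cols, collapse = ", ")))
  }
  if (is.null(data$occ)) data$occ <- 1L
  row_fail <- function(cond, what) {
    if (any(cond, na.rm = TRUE)) {
      abort(sprintf("%s (row%s %s)", what,
                    if (sum(cond, na.rm = TRUE) > 1) "s" else "",
                    paste(utils::head(which(cond), 5), collapse = ", ")))
    }
  }
  row_fail(!data$evid %in% c(0L, 1L), "evid must be 0 or 1")
  row_fail(!is.finite(data$time) | data$time < 0,
           "times must be non-negative")
  nonmono <- unlist(lapply(split(seq_len(nrow(data)), data$id), function(i) {
    i[c(FALSE, diff(data$time[i]) < 0)]
  }))
  bad <- rep(FALSE, nrow(data)); bad[nonmono] <- TRUE
  row_fail(bad, "times must be non-decreasing within subject")
  row_fail(data$evid == 1L & (is.na(data$amt) | data$amt <= 0),
           "dose rows must have amt > 0")
  row_fail(data$evid == 1L & !is.na(data$dv),
           "dose rows must not carry a DV")
  row_fail(data$evid == 0L & data$mdv == 0L & is.na(data$dv),
           "observation rows with mdv 0 must carry a DV")
  row_fail(data$evid == 0L & !is.na(data$dv) & data$dv < 0,
           "concentrations must be non-negative")
  data
}
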
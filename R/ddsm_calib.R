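# DDSM film-mammography bookkeeping: per-scanner optical-density
# calibration and case-volume summaries.

ddsm_scanners <- list(
  "DBA M2100 ImageClear" = list(
    sampling_microns = 42, bits = 16L, form = "log10",
    a = 4.26700423014133, b = -0.90303289757264),
  "Howtek 960" = list(
    sampling_microns = 43.5, bits = 12L, form = "linear",
    a = 3.78928997845071, b = -0.00094568009377),
  "Lumisys 200 Laser" = list(
    sampling_microns = 50, bits = 12L, form = "linear",
    a = 4.05977749300340, b = -0.00099080941710),
  "Howtek MultiRad850" = list(
    sampling_microns = 43.5, bits = 12L, form = "linear",
    a = 3.96604095240593, b = -0.00099055807612)
)

#' Built-in DDSM scanner calibrations
#'
#' The four film digitizers used for the DDSM archive, with their sampling
#' rate, bit depth, and the coefficients of the gray-value to
#' optical-density calibration: `OD = a + b * log10(GV)` for the DBA
#' scanner and `OD = a + b * GV` for the three linear scanners.
#'
#' @return data.frame with columns `scanner`, `sampling_microns`, `bits`,
#'   `form`, `a`, `b`.
#' @export
scanner_calibrations <- function() {
  do.call(rbind, lapply(names(ddsm_scanners), function(nm) {
    s <- ddsm_scanners[[nm]]
    data.frame(scanner = nm, sampling_microns = s$sampling_microns,
               bits = s$bits, form = s$form, a = s$a, b = s$b)
  }))
}

#' Convert scanner gray values to optical density
#'
#' @param scanner one of the names in [scanner_calibrations()].
#' @param gray_value numeric vector of gray values, within the scanner's
#'   bit range; must be strictly positive for the log10-form DBA scanner.
#' @return Optical density values (unitless film-darkness measure; higher
#'   OD = darker film = lower gray value).
#' @examples
#' gv_to_od("Howtek 960", 0)      # the calibration intercept
#' gv_to_od("DBA M2100 ImageClear", 1e4)
#' @export
gv_to_od <- function(scanner, gray_value) {
  s <- ddsm_scanners[[scanner]]
  if (is.null(s)) {
    stop(sprintf("unknown scanner '%s'; see scanner_calibrations()", scanner),
         call. = FALSE)
  }
  gmax <- 2^s$bits - 1
  if (any(gray_value < 0 | gray_value > gmax)) {
    stop(sprintf("gray values must lie in [0, %d] for %s", gmax, scanner),
         call. = FALSE)
  }
  if (s$form == "log10") {
    if (any(gray_value <= 0)) {
      stop("gray value must be positive for a log10-form calibration",
           call. = FALSE)
    }
    s$a + s$b * log10(gray_value)
  } else {
    s$a + s$b * gray_value
  }
}

ddsm_severities <- c("normal", "benign without callback", "benign",
                     "malignant")

#' DDSM case counts by institution and most severe finding
#'
#' Archive composition of the 2620 screening examinations: contributing
#' institution, digitizer, and per-severity case counts.
#'
#' @return data.frame with columns `institution`, `digitizer`, `severity`,
#'   `n`.
#' @export
ddsm_volume_counts <- function() {
  rows <- list(
    c("MGH", "DBA M2100 ImageClear", 430, 0, 0, 97),
    c("MGH", "Howtek 960", 78, 0, 446, 323),
    c("WFU", "Lumisys 200 Laser", 82, 93, 126, 159),
    c("SH", "Lumisys 200 Laser", 0, 48, 202, 234),
    c("WU", "Howtek MultiRad850", 105, 0, 96, 101)
  )
  do.call(rbind, lapply(rows, function(r) {
    data.frame(institution = r[1], digitizer = r[2],
               severity = ddsm_severities, n = as.integer(r[3:6]))
  }))
}

#' Summarise case records by institution and severity
#'
#' Builds the contingency table of case counts by institution (rows) and
#' most-severe-finding volume (columns), with row, column and grand totals.
#'
#' @param records data.frame with columns `institution` and `severity`
#'   (severity must be one of `"normal"`, `"benign without callback"`,
#'   `"benign"`, `"malignant"`), one row per case; or a pre-counted
#'   data.frame that additionally has an `n` column.
#' @return A list of class `volume_summary`: `table` (matrix with margin
#'   totals), `grand_total`.
#' @export
volume_summary <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("institution", "severity") %in% names(records)))
  bad <- setdiff(unique(records$severity), ddsm_severities)
  if (length(bad) > 0) {
    stop("unknown severity label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  insts <- unique(records$institution)
  tab <- matrix(0L, nrow = length(insts), ncol = length(ddsm_severities),
                dimnames = list(insts, ddsm_severities))
  w <- if ("n" %in% names(records)) records$n else rep(1L, nrow(records))
  for (k in seq_len(nrow(records))) {
    tab[records$institution[k], records$severity[k]] <-
      tab[records$institution[k], records$severity[k]] + w[k]
  }
  out <- rbind(cbind(tab, Total = rowSums(tab)),
               Total = c(colSums(tab), sum(tab)))
  structure(list(table = out, grand_total = sum(tab)),
            class = "volume_summary")
}

#' @export
print.volume_summary <- function(x, ...) {
  cat("Cases by institution and most severe finding\n")
  print(x$table)
  invisible(x)
}

#' Read or write DDSM-style case records as CSV
#'
#' Columns: `institution`, `digitizer`, `severity`, `patient_age`,
#' `exam_date`, `acr_density`. Only `institution` and `severity` are
#' required for [volume_summary()].
#'
#' @param records data.frame of case records.
#' @param path CSV file path.
#' @return `read_case_records()` returns a validated data.frame.
#' @export
write_case_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_case_records
#' @export
read_case_records <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("institution", "severity") %in% names(rec))) {
    stop("case records need `institution` and `severity` columns",
         call. = FALSE)
  }
  bad <- setdiff(unique(rec$severity), ddsm_severities)
  if (length(bad) > 0) {
    stop("unknown severity label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rec
}
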
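#' Construct a localization table
#'
#' A localization table holds one row per MINFLUX localization with its
#' emission-trace label, acquisition time, 2D position in nanometers, and
#' the two quality metrics used for filtering: `efo_hz` (background-
#' corrected emission rate) and `cfr` (center frequency ratio).
#'
#' @param df data.frame with columns `trace_id`, `time`, `x_nm`, `y_nm`,
#'   `efo_hz`, `cfr`.
#' @param metadata named list of free-form metadata (e.g. field-of-view
#'   bounds `fov_xmin` .. `fov_ymax` in nm, condition label, seed).
#' @return A `loc_table`: a data.frame with a `metadata` attribute.
#' @export
loc_table <- function(df, metadata = list()) {
  req <- c("trace_id", "time", "x_nm", "y_nm", "efo_hz", "cfr")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("localization table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[req]
  for (cl in req) {
    if (!is.numeric(df[[cl]])) {
      stop(sprintf("column '%s' must be numeric", cl), call. = FALSE)
    }
  }
  if (nrow(df)) {
    if (any(!is.finite(df$x_nm)) || any(!is.finite(df$y_nm))) {
      stop("coordinates must be finite", call. = FALSE)
    }
    if (any(df$efo_hz < 0) || any(df$cfr < 0)) {
      stop("efo_hz and cfr must be non-negative", call. = FALSE)
    }
    fov <- metadata[c("fov_xmin", "fov_xmax", "fov_ymin", "fov_ymax")]
    if (!any(vapply(fov, is.null, logical(1)))) {
      fov <- lapply(fov, as.numeric)
      if (min(df$x_nm) < fov$fov_xmin || max(df$x_nm) > fov$fov_xmax ||
          min(df$y_nm) < fov$fov_ymin || max(df$y_nm) > fov$fov_ymax) {
        stop("field-of-view bounds in metadata do not contain all coordinates",
             call. = FALSE)
      }
    }
  }
  df$trace_id <- as.integer(df$trace_id)
  rownames(df) <- NULL
  attr(df, "metadata") <- metadata
  class(df) <- c("loc_table", "data.frame")
  df
}

#' @export
print.loc_table <- function(x, ...) {
  tr <- length(unique(x$trace_id))
  cat(sprintf("MINFLUX localization table: %d localizations in %d traces\n",
              nrow(x), tr))
  md <- attr(x, "metadata")
  if (length(md)) {
    cat("metadata:", paste(names(md), unlist(md), sep = "=", collapse = "; "),
        "\n")
  }
  if (nrow(x)) print(utils::head(as.data.frame(x), 5L))
  invisible(x)
}

#' Read a localization table from CSV
#'
#' The supported dialect is a plain CSV with header
#' `trace_id,time,x_nm,y_nm,efo_hz,cfr`. Metadata may precede the header as
#' `# key: value` comment lines. A `z` / `z_nm` column, if present, is
#' dropped with a warning: the analysis is strictly 2D. Row order is
#' preserved exactly.
#'
#' @param path CSV file path.
#' @param dialect only `"generic-csv"` is implemented; the argument exists
#'   so vendor-export readers can be added without changing call sites.
#' @return A [loc_table()].
#' @export
read_localizations <- function(path, dialect = "generic-csv") {
  dialect <- match.arg(dialect, "generic-csv")
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta <- parse_metadata(lines[is_meta])
  body <- lines[!is_meta]
  if (!length(body)) stop("no header row in ", path, call. = FALSE)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE, check.names = FALSE)
  zcols <- intersect(c("z", "z_nm"), names(df))
  if (length(zcols)) {
    warning("dropping z column(s) (2D analysis): ",
            paste(zcols, collapse = ", "), call. = FALSE)
    df <- df[setdiff(names(df), zcols)]
  }
  req <- c("trace_id", "time", "x_nm", "y_nm", "efo_hz", "cfr")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("format error: missing column(s) ", paste(miss, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  for (cl in req) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("parse error: non-numeric value in column '%s', row %d",
                     cl, bad[1]), call. = FALSE)
      }
      df[[cl]] <- num
    }
  }
  loc_table(df, metadata = meta)
}

parse_metadata <- function(lines) {
  lines <- sub("^#\\s*", "", lines)
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  meta <- list()
  for (m in kv) {
    if (length(m) == 3L) {
      val <- m[3]
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(m[2])]] <- if (!is.na(num)) num else val
    }
  }
  meta
}

format_num <- function(v) {
  out <- vapply(v, function(z) {
    if (is.finite(z) && z == round(z) && abs(z) < 2^53) {
      format(z, scientific = FALSE)
    } else {
      sprintf("%.17g", z)
    }
  }, character(1))
  out
}

write_table_csv <- function(df, path, metadata = list()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in names(metadata)) {
    writeLines(sprintf("# %s: %s", k, format(metadata[[k]], digits = 17)), con)
  }
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df)) {
    cols <- lapply(df, function(v) if (is.numeric(v)) format_num(v) else as.character(v))
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  }
  invisible(NULL)
}

#' Write a localization table to CSV
#'
#' Full floating-point precision is preserved (round-trip exact well below
#' 1e-9 nm); metadata is written as `# key: value` lines above the header.
#'
#' @param table a [loc_table()].
#' @param path output path.
#' @export
write_localizations <- function(table, path) {
  table <- loc_table(table, attr(table, "metadata") %||% list())
  write_table_csv(as.data.frame(table), path,
                  metadata = attr(table, "metadata") %||% list())
}

#' Read / write trace-center sets
#'
#' Trace centers travel as CSV with header `trace_id,n_locs,x_nm,y_nm`.
#'
#' @param path CSV file path.
#' @return `read_trace_centers`: a `trace_centers` data.frame.
#' @export
read_trace_centers <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  df <- utils::read.csv(text = paste(lines[!is_meta], collapse = "\n"))
  req <- c("trace_id", "n_locs", "x_nm", "y_nm")
  miss <- setdiff(req, names(df))
  if (length(miss)) {
    stop("format error: missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  new_trace_centers(df[req], provenance = parse_metadata(lines[is_meta]))
}

#' @param centers a `trace_centers` object.
#' @rdname read_trace_centers
#' @export
write_trace_centers <- function(centers, path) {
  write_table_csv(as.data.frame(centers)[c("trace_id", "n_locs", "x_nm", "y_nm")],
                  path)
}

#' Write a Ripley curve as CSV
#'
#' Columns `r_nm,K,L,H`, one row per radius.
#'
#' @param curve a `ripley_curve` (see [ripley_h()]).
#' @param path output path.
#' @export
write_ripley_csv <- function(curve, path) {
  df <- as.data.frame(curve)[c("r_nm", "K", "L", "H")]
  write_table_csv(df, path)
}

#' Write / read a pipeline summary report
#'
#' The report is serialized as JSON with full numeric precision. If the
#' report contains a Ripley curve it is additionally written as a
#' two-column `r_nm,H` CSV next to the JSON file (suffix `_ripley.csv`),
#' or to `curve_path` if given.
#'
#' @param report a `flux_report` from [run_pipeline()].
#' @param path output JSON path.
#' @param curve_path optional path for the Ripley H CSV sidecar.
#' @export
write_report <- function(report, path, curve_path = NULL) {
  json <- report_json(report)
  writeLines(json, path)
  if (!is.null(report$ripley)) {
    if (is.null(curve_path)) {
      curve_path <- paste0(sub("\\.json$", "", path), "_ripley.csv")
    }
    write_table_csv(data.frame(r_nm = report$ripley$r_nm,
                               H = report$ripley$H), curve_path)
  }
  invisible(path)
}

report_json <- function(report) {
  x <- unclass(report)
  if (!is.null(x$ripley)) x$ripley <- as.data.frame(x$ripley)
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                   na = "null", pretty = TRUE)
}

#' @rdname write_report
#' @return `read_report`: the report as a list (class `flux_report`).
#' @export
read_report <- function(path) {
  x <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE)
  class(x) <- "flux_report"
  x
}
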
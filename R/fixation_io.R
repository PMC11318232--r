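#' Column-name mapping for fixation tables
#'
#' Eye-tracker vendors name their export columns differently; the default
#' follows the Pupil Labs `fixations.csv` schema. Override any entry to
#' absorb another vendor's naming.
#'
#' @param id,start_timestamp,duration,norm_x,norm_y Column names in the file.
#' @return A named character vector used by [read_fixation_csv()].
#' @export
fixation_columns <- function(id = "id", start_timestamp = "start_timestamp",
                             duration = "duration", norm_x = "norm_pos_x",
                             norm_y = "norm_pos_y") {
  c(fixation_id = id, start_timestamp = start_timestamp,
    duration_ms = duration, norm_x = norm_x, norm_y = norm_y)
}

#' Read a fixation table
#'
#' Reads a comma-separated fixation export (header row required) into the
#' canonical schema: `fixation_id`, `start_timestamp` (seconds),
#' `duration_ms`, `norm_x`, `norm_y` in `[0,1]` normalised image
#' coordinates. Row order — the order in which the fixations were made — is
#' preserved, and every unknown column is kept as a passthrough column so it
#' survives to the projection output.
#'
#' @param path Path to the CSV file.
#' @param columns Mapping from canonical to file column names, see
#'   [fixation_columns()].
#' @return A tibble of class `fixation_table`.
#' @export
read_fixation_csv <- function(path, columns = fixation_columns()) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(unname(columns), names(raw))
  if (length(missing) > 0) {
    stop("fixation table is missing mandatory column(s): ",
         paste(missing, collapse = ", "))
  }
  for (col in columns[c("norm_x", "norm_y", "start_timestamp", "duration_ms")]) {
    vals <- raw[[col]]
    if (!is.numeric(vals) && nrow(raw) > 0) {
      bad <- which(is.na(suppressWarnings(as.numeric(vals))))
      stop("non-numeric value in column '", col, "' at data row ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  out <- tibble::tibble(
    fixation_id = raw[[columns[["fixation_id"]]]],
    start_timestamp = as.numeric(raw[[columns[["start_timestamp"]]]]),
    duration_ms = as.numeric(raw[[columns[["duration_ms"]]]]),
    norm_x = as.numeric(raw[[columns[["norm_x"]]]]),
    norm_y = as.numeric(raw[[columns[["norm_y"]]]])
  )
  if (anyDuplicated(out$fixation_id)) {
    stop("fixation_id values are not unique")
  }
  stopifnot(all(out$duration_ms >= 0))
  passthrough <- raw[setdiff(names(raw), unname(columns))]
  out <- dplyr::bind_cols(out, passthrough)
  class(out) <- c("fixation_table", class(out))
  out
}

#' Write a fixation table in the vendor schema
#'
#' Inverse of [read_fixation_csv()] under the same column mapping; used by
#' the synthetic harness to emit tables any downstream consumer can read.
#'
#' @param fixations A `fixation_table` (or compatible tibble).
#' @param path Output path.
#' @param columns See [fixation_columns()].
#' @return `path`, invisibly.
#' @export
write_fixation_csv <- function(fixations, path, columns = fixation_columns()) {
  out <- fixations
  canon <- names(columns)
  names(out)[match(canon, names(out))] <- unname(columns)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# machine-readable status -> CSV literal; the no-intersection wording is the
# fixed vocabulary downstream tools key on
.status_literals <- c(
  mapped = "mapped",
  no_intersection = "no intersection between fixation vector and model",
  frame_not_registered = "frame not registered"
)

#' Status vocabulary of the projection output
#'
#' @return Named character vector mapping internal status codes to the
#'   literals written in the CSV `status` column.
#' @export
status_literals <- function() .status_literals

#' Write the projection result table to CSV
#'
#' One row per fixation, in fixation order. Columns: `fixation_id`; the
#' intersection point (`intersection_x/y/z`, empty when the beam missed);
#' the beam origin (`fixation_start_x/y/z` — the world-camera position when
#' the fixation was detected); the beam direction
#' (`fixation_direction_x/y/z`, unit vector); `status` (see
#' [status_literals()]); then every passthrough eye-tracker column.
#'
#' @param projections A projection table from [project_fixations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_projection_csv <- function(projections, path) {
  out <- projections
  out$status <- unname(.status_literals[out$status])
  out$ray_t <- NULL
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read a projection result table written by [write_projection_csv()]
#'
#' @param path Path to the CSV.
#' @return A tibble with internal status codes restored.
#' @export
read_projection_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  codes <- names(.status_literals)[match(out$status, .status_literals)]
  if (anyNA(codes)) stop("unknown status literal in projection table")
  out$status <- codes
  class(out) <- c("projection_table", class(out))
  out
}
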
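#' Build a school sampling frame
#'
#' A sampling frame lists the eligible schools of the survey area (as
#' obtained from a ministry of education or equivalent authority) with
#' their enrollment counts. Schools are the primary sampling units;
#' selection probability is proportional to enrollment, so the frame must
#' carry an accurate pupil count per school. Optional year-group columns
#' (\code{yg_1 ... yg_k}) allow the second sampling stage to spread the
#' cluster quota across year groups; when present they must sum to the
#' school's enrollment.
#'
#' Zero-enrollment schools are retained (so frame row numbers match the
#' source) but flagged: they have zero selection probability and can never
#' be drawn.
#'
#' @param records A data frame with columns \code{school_id},
#'   \code{enrollment}, optional \code{name} and optional year-group
#'   columns \code{yg_*}.
#' @return An object of class \code{"sehra_frame"}: the validated data
#'   frame with attributes \code{total_enrollment} and \code{yg_cols}.
#' @examples
#' school_frame(data.frame(school_id = c("A", "B", "C"),
#'                         enrollment = c(300, 100, 100)))
#' @export
school_frame <- function(records) {
  if (!is.data.frame(records))
    stop("'records' must be a data frame", call. = FALSE)
  for (col in c("school_id", "enrollment"))
    if (!col %in% names(records))
      stop(sprintf("frame is missing required column '%s'", col),
           call. = FALSE)
  records$school_id <- as.character(records$school_id)
  if (anyDuplicated(records$school_id)) {
    dup <- records$school_id[duplicated(records$school_id)][1L]
    stop(sprintf("duplicate school_id '%s' in frame", dup), call. = FALSE)
  }
  enr <- records$enrollment
  if (!is.numeric(enr) || anyNA(enr) || any(enr < 0) || any(enr != round(enr)))
    stop("'enrollment' must be non-negative whole numbers", call. = FALSE)
  records$enrollment <- as.integer(enr)
  yg_cols <- grep("^yg_", names(records), value = TRUE)
  if (length(yg_cols)) {
    yg <- as.matrix(records[yg_cols])
    if (anyNA(yg) || any(yg < 0) || any(yg != round(yg)))
      stop("year-group counts must be non-negative whole numbers",
           call. = FALSE)
    bad <- which(rowSums(yg) != records$enrollment)
    if (length(bad))
      stop(sprintf(
        "year-group counts do not sum to enrollment for school '%s' (row %d)",
        records$school_id[bad[1L]], bad[1L]), call. = FALSE)
  }
  structure(records,
            total_enrollment = sum(records$enrollment),
            yg_cols = yg_cols,
            class = c("sehra_frame", "data.frame"))
}

#' Read a school sampling frame from CSV
#'
#' Expects columns \code{school_id} and \code{enrollment}; \code{name} and
#' year-group columns \code{yg_1 ... yg_k} are optional. Lines starting
#' with \code{#} are treated as comments. Validation is as in
#' [school_frame()].
#'
#' @param path Path to the CSV file.
#' @return A \code{"sehra_frame"} object.
#' @examples
#' frame <- read_school_frame(
#'   system.file("extdata", "demo_school_frame.csv", package = "sehra"))
#' total_enrollment(frame)
#' @export
read_school_frame <- function(path) {
  if (!file.exists(path))
    stop(sprintf("frame file not found: '%s'", path), call. = FALSE)
  school_frame(read.csv(path, comment.char = "#", stringsAsFactors = FALSE))
}

#' @rdname school_frame
#' @param frame A \code{"sehra_frame"} object.
#' @export
total_enrollment <- function(frame) {
  stopifnot(inherits(frame, "sehra_frame"))
  attr(frame, "total_enrollment")
}

#' @export
print.sehra_frame <- function(x, ...) {
  cat(sprintf("School sampling frame: %d schools, %d pupils enrolled\n",
              nrow(x), attr(x, "total_enrollment")))
  nzero <- sum(x$enrollment == 0L)
  if (nzero)
    cat(sprintf("  (%d zero-enrollment school%s retained but never selectable)\n",
                nzero, if (nzero > 1) "s" else ""))
  if (length(attr(x, "yg_cols")))
    cat(sprintf("  year-group counts present (%d groups)\n",
                length(attr(x, "yg_cols"))))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("  ... %d more schools\n", nrow(x) - 5L))
  invisible(x)
}
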
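#' Construct a network time-course table
#'
#' The basic data container of the pipeline: one recording's network time
#' courses as a frames x networks matrix, together with the repetition time
#' and recording metadata (subject, group/condition, cohort split).
#'
#' @param values numeric matrix, frames x networks; no missing values.
#' @param tr repetition time in seconds.
#' @param subject subject identifier.
#' @param group condition label, one of `"AWAKE"`, `"PROP"`, `"SEVO"`, `"UWS"`.
#' @param cohort `"train"` or `"test"` (anesthesia vs. UWS/control split),
#'   or `NA` when not applicable.
#' @return an object of class `time_course_table`.
#' @export
time_course_table <- function(values, tr, subject = NA_character_,
                              group = NA_character_, cohort = NA_character_) {
  values <- as.matrix(values)
  stop_if_not(is.numeric(values), "time-course values must be numeric")
  stop_if_not(nrow(values) >= 1 && ncol(values) >= 1,
              "a recording needs at least one frame and one network")
  stop_if_not(!anyNA(values) && all(is.finite(values)),
              "time-course values must be finite and non-missing")
  stop_if_not(is.numeric(tr) && length(tr) == 1 && tr > 0,
              "tr must be a positive scalar (seconds)")
  if (!is.na(group)) {
    stop_if_not(group %in% c("AWAKE", "PROP", "SEVO", "UWS"),
                "unknown group label '%s'", group)
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("N%02d", seq_len(ncol(values)))
  }
  structure(
    list(values = values, tr = tr, subject = subject,
         group = group, cohort = cohort),
    class = "time_course_table"
  )
}

#' @export
print.time_course_table <- function(x, ...) {
  cat(sprintf("<time_course_table> %d frames x %d networks, TR = %gs",
              nrow(x$values), ncol(x$values), x$tr))
  if (!is.na(x$subject)) cat(sprintf(", subject %s", x$subject))
  if (!is.na(x$group)) cat(sprintf(" [%s]", x$group))
  cat("\n")
  invisible(x)
}

#' @export
dim.time_course_table <- function(x) dim(x$values)

n_frames <- function(table) nrow(table$values)
n_networks <- function(table) ncol(table$values)
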
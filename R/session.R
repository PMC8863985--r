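#' Longitudinal session metadata
#'
#' One scanning session of one infant: a subject identifier, an age in days,
#' and an optional timepoint label. When both age and timepoint are given
#' they must be consistent: newborn (`"0m"`) up to 60 days, `"3m"` 61-150
#' days, `"6m"` above 150 days.
#'
#' @param subject_id Character token identifying the subject.
#' @param age_days Non-negative integer age at scan.
#' @param timepoint Optional timepoint tag: `"0m"`, `"3m"` or `"6m"`.
#' @return A `session_meta` object.
#' @export
session_meta <- function(subject_id, age_days, timepoint = NULL) {
  stopifnot(is.character(subject_id), length(subject_id) == 1L,
            nzchar(subject_id))
  age_days <- as.integer(age_days)
  if (is.na(age_days) || age_days < 0L) stop("age_days must be >= 0")
  if (!is.null(timepoint)) {
    timepoint <- match.arg(timepoint, c("0m", "3m", "6m"))
    ok <- switch(timepoint,
                 "0m" = age_days <= 60L,
                 "3m" = age_days >= 61L && age_days <= 150L,
                 "6m" = age_days > 150L)
    if (!ok)
      stop(sprintf("age_days = %d is inconsistent with timepoint '%s'",
                   age_days, timepoint))
  }
  structure(list(subject_id = subject_id, age_days = age_days,
                 timepoint = timepoint),
            class = "session_meta")
}

#' @export
print.session_meta <- function(x, ...) {
  cat(sprintf("<session_meta> %s, %d days%s\n", x$subject_id, x$age_days,
              if (is.null(x$timepoint)) "" else paste0(" (", x$timepoint, ")")))
  invisible(x)
}
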
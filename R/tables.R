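#' Long-format tract-profile tables
#'
#' The tabular interchange format of the package: one row per
#' (bundle, node, metric) with the session metadata and the node's core
#' coordinate. Deterministic row order (bundle name, then node) so that
#' repeated runs produce byte-identical files.
#'
#' @param profiles List of [tract_profile] objects (all with the same node
#'   count).
#' @param meta A [session_meta].
#' @return A data.frame with columns subject, age_days, timepoint, bundle,
#'   node (1-based), metric, value, se, n_contrib, x, y, z.
#' @export
profile_table <- function(profiles, meta) {
  stopifnot(length(profiles) > 0L)
  nn <- vapply(profiles, function(p) p$n_nodes, integer(1))
  if (length(unique(nn)) != 1L)
    stop("all profiles must share the same node count")
  rows <- lapply(profiles, function(p) {
    data.frame(subject = meta$subject_id,
               age_days = meta$age_days,
               timepoint = if (is.null(meta$timepoint)) NA_character_
                           else meta$timepoint,
               bundle = p$bundle,
               node = seq_len(p$n_nodes),
               metric = p$metric,
               value = p$value_mean,
               se = p$value_se,
               n_contrib = p$n_contrib,
               x = p$core_xyz[, 1], y = p$core_xyz[, 2], z = p$core_xyz[, 3],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$bundle, tab$metric, tab$node), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Write / read a profile table as CSV
#'
#' Values are written with full double precision (`format = "%.17g"` via R's
#' default `write.csv` representation is insufficient, so numbers are
#' formatted explicitly) and round-trip to within 1e-9.
#'
#' @param profiles List of [tract_profile]s, or an already-built data.frame
#'   from [profile_table].
#' @param meta A [session_meta] (ignored when `profiles` is a data.frame).
#' @param path Output CSV path.
#' @return `path` invisibly; `read_profile_table` returns the data.frame.
#' @export
write_profile_table <- function(profiles, meta = NULL, path) {
  tab <- if (is.data.frame(profiles)) profiles else profile_table(profiles, meta)
  num <- vapply(tab, is.numeric, logical(1))
  out <- tab
  for (j in which(num)) {
    if (names(tab)[j] %in% c("age_days", "node", "n_contrib")) next
    out[[j]] <- sprintf("%.17g", tab[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_profile_table
#' @export
read_profile_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("value", "se", "x", "y", "z"))
    if (col %in% names(tab)) tab[[col]] <- as.numeric(tab[[col]])
  tab
}
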
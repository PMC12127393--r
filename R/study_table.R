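# Study-level data model: one row per primary study with sample size, the
# available pairwise correlations among physical activity (PA), self-control
# (SC) and mobile-phone addiction (MPA), and categorical moderators.

.PAIRS <- c("pa_mpa", "pa_sc", "sc_mpa")
.R_COLS <- paste0("r_", .PAIRS)
.REQUIRED_COLS <- c("study_id", "n", .R_COLS)
.MODERATOR_COLS <- c("educational_stage", "region", "scale_pair")

# Validates a data frame of study records; returns it classed as study_table.
# Row-indexed diagnostics are collected and reported together so a malformed
# table fails with every problem named, not just the first.
as_study_table <- function(df) {
  if (!is.data.frame(df))
    stop("study table must be a data frame")
  missing_cols <- setdiff(.REQUIRED_COLS, names(df))
  if (length(missing_cols) > 0L)
    stop("study table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  df$study_id <- as.character(df$study_id)
  problems <- character(0)
  for (i in seq_len(nrow(df))) {
    id <- df$study_id[i]
    n <- df$n[i]
    if (is.na(n) || !is.finite(n) || n < 4 || n != round(n))
      problems <- c(problems, sprintf(
        "row %d (study '%s'): n must be an integer >= 4 (got %s); 1/(n-3) would not be a valid variance",
        i, id, format(n)))
    rs <- unlist(df[i, .R_COLS])
    present <- !is.na(rs)
    if (!any(present))
      problems <- c(problems, sprintf(
        "row %d (study '%s'): at least one of %s must be present",
        i, id, paste(.R_COLS, collapse = ", ")))
    bad <- present & abs(rs) >= 1 - 1e-12
    if (any(bad))
      problems <- c(problems, sprintf(
        "row %d (study '%s'): %s outside (-1, 1); Fisher's z is undefined",
        i, id, paste(.R_COLS[bad], collapse = ", ")))
  }
  if (length(problems) > 0L)
    stop("invalid study table:\n  ", paste(problems, collapse = "\n  "))
  class(df) <- c("study_table", "data.frame")
  df
}

#' Read a study-level correlation table from CSV
#'
#' The expected dialect is UTF-8, comma-separated, with `"NA"` or an empty
#' field marking a missing value. Mandatory columns: `study_id`, `n`,
#' `r_pa_mpa`, `r_pa_sc`, `r_sc_mpa`. Optional columns (kept when present):
#' `educational_stage`, `region`, `scale_pair`, `year`, `dup_group`.
#'
#' Every row is validated: `n` must be an integer of at least 4 (so the
#' Fisher-z variance 1/(n-3) exists), each reported correlation must lie
#' strictly inside (-1, 1), and at least one of the three correlations must
#' be present. Violations are reported with row indices and study ids.
#'
#' @param path Path to a CSV file.
#' @return A `study_table` data frame.
#' @seealso [write_study_table()], [simulate_studies()]
#' @export
read_study_table <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""), fileEncoding = "UTF-8")
  as_study_table(df)
}

#' Write a study table to CSV
#'
#' Inverse of [read_study_table()]: the written file reads back to identical
#' records.
#'
#' @param studies A `study_table` data frame (or anything [as_study_table()]
#'   accepts).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(studies, path) {
  studies <- as_study_table(as.data.frame(studies))
  utils::write.csv(studies, path, row.names = FALSE, na = "NA",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Collapse sub-dimension correlations into a single study-level correlation
#'
#' When a primary study reports correlations only for individual sub-scales
#' of a multi-dimensional instrument, the study-level effect is coded as the
#' arithmetic mean of the reported raw correlations. The mean is taken on the
#' raw r scale (not the Fisher-z scale): that is the plain reading of the
#' coding rule, and the difference is negligible for |r| < 0.6.
#'
#' @param rs Non-empty numeric vector of correlations, each strictly inside
#'   (-1, 1).
#' @return A single correlation.
#' @examples
#' collapse_dimensions(c(0.2, 0.4))   # 0.3
#' @export
collapse_dimensions <- function(rs) {
  if (!is.numeric(rs) || length(rs) == 0L)
    stop("'rs' must be a non-empty numeric vector of correlations")
  if (anyNA(rs) || any(abs(rs) >= 1 - 1e-12))
    stop("every sub-dimension correlation must lie strictly inside (-1, 1)")
  mean(rs)
}

#' Resolve duplicate samples by earliest publication
#'
#' When several records share the same underlying sample, the first published
#' one is kept. Ties on year are broken deterministically by lexicographic
#' `study_id` order.
#'
#' @param duplicates Data frame of records from one duplicate group; must
#'   have columns `study_id` and `year`.
#' @return The selected record (one-row data frame).
#' @export
select_first_published <- function(duplicates) {
  if (!is.data.frame(duplicates) || nrow(duplicates) == 0L)
    stop("'duplicates' must be a non-empty data frame")
  if (!all(c("study_id", "year") %in% names(duplicates)))
    stop("'duplicates' must have columns 'study_id' and 'year'")
  ord <- order(duplicates$year, as.character(duplicates$study_id))
  duplicates[ord[1L], , drop = FALSE]
}

#' Extract the effect sizes for one variable pair from a study table
#'
#' Returns the studies reporting the requested correlation, ready to be
#' passed to [meta_pool()].
#'
#' @param studies A `study_table` data frame.
#' @param pair One of `"pa_mpa"`, `"pa_sc"`, `"sc_mpa"`.
#' @return Data frame with columns `study_id`, `r`, `n` (one row per study
#'   reporting the pair).
#' @export
study_effects <- function(studies, pair = c("pa_mpa", "pa_sc", "sc_mpa")) {
  pair <- match.arg(pair)
  studies <- as_study_table(as.data.frame(studies))
  col <- paste0("r_", pair)
  keep <- !is.na(studies[[col]])
  data.frame(study_id = studies$study_id[keep],
             r = studies[[col]][keep],
             n = studies$n[keep],
             stringsAsFactors = FALSE)
}
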
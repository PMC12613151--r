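# Transition-report interchange: the long CSV dialect the pipeline consumes,
# one row per (sample, lipid, transition). Columns:
#   sample_id, lipid, transition_type (MS1|fragment), isomer, fragment,
#   area, rt, mobility
# MS1 rows carry the precursor area (isomer/fragment empty); fragment rows
# carry one diagnostic fragment area attributed to one contributing isomer.

.REPORT_COLS <- c("sample_id", "lipid", "transition_type", "isomer",
                  "fragment", "area", "rt", "mobility")

#' Read a transition report into peak groups
#'
#' Rows are grouped by (sample, precursor lipid); every group must contain
#' exactly one MS1 row. Row-level problems (unparseable lipid names,
#' negative areas, duplicate transition keys) are collected and reported
#' together, addressed by row number. Groups lacking fragment rows are kept
#' with a warning.
#'
#' @param path CSV path in the dialect above.
#' @return named list of [peak_group()] objects, keyed
#'   `"<sample_id>|<lipid>"`. An empty file returns an empty list with a
#'   warning.
#' @export
read_transition_report <- function(path) {
  if (!file.exists(path)) stop_snlipid("io", "no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0L) {
    warning("empty transition report: ", path, call. = FALSE)
    return(list())
  }
  missing_cols <- setdiff(.REPORT_COLS, names(df))
  if (length(missing_cols) > 0L)
    stop_snlipid("io", "transition report lacks columns: %s",
                 paste(missing_cols, collapse = ", "))
  df$area <- suppressWarnings(as.numeric(df$area))
  df$rt <- suppressWarnings(as.numeric(df$rt))
  df$mobility <- suppressWarnings(as.numeric(df$mobility))

  errs <- character()
  for (i in seq_len(nrow(df))) {
    tryCatch(parse_lipid(df$lipid[i]), error = function(e) {
      errs <<- c(errs, sprintf("row %d: %s", i, conditionMessage(e)))
    })
    if (is.na(df$area[i]) || df$area[i] < 0)
      errs <- c(errs, sprintf("row %d (%s): negative or missing area",
                              i, df$lipid[i]))
    if (!df$transition_type[i] %in% c("MS1", "fragment"))
      errs <- c(errs, sprintf("row %d: unknown transition_type '%s'",
                              i, df$transition_type[i]))
  }
  key <- paste(df$sample_id, df$lipid, df$transition_type, df$isomer,
               df$fragment, sep = "|")
  dup <- which(duplicated(key))
  for (i in dup)
    errs <- c(errs, sprintf("row %d: duplicate transition key '%s'",
                            i, key[i]))
  if (length(errs) > 0L)
    stop_snlipid("io", "transition report validation failed:\n  %s",
                 paste(errs, collapse = "\n  "))

  gkey <- paste(df$sample_id, df$lipid, sep = "|")
  groups <- list()
  for (k in unique(gkey)) {
    sub <- df[gkey == k, , drop = FALSE]
    ms1 <- sub[sub$transition_type == "MS1", , drop = FALSE]
    if (nrow(ms1) != 1L)
      stop_snlipid("io", "group '%s' needs exactly one MS1 row, found %d",
                   k, nrow(ms1))
    frag <- sub[sub$transition_type == "fragment", , drop = FALSE]
    if (nrow(frag) == 0L)
      warning("group '", k, "' has no fragment rows", call. = FALSE)
    groups[[k]] <- peak_group(
      sample_id = ms1$sample_id, precursor = ms1$lipid,
      ms1_area = ms1$area,
      fragments = data.frame(isomer = frag$isomer,
                             fragment = frag$fragment,
                             area = frag$area),
      rt = ms1$rt, mobility = ms1$mobility)
  }
  groups
}

#' Write peak groups as a transition report
#'
#' Exact inverse of [read_transition_report()]: writing then re-reading any
#' in-memory report reproduces it. Rows are ordered deterministically
#' (sample, lipid, MS1 before fragments, fragment label) with fixed float
#' formatting.
#'
#' @param groups list of [peak_group()] objects.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_transition_report <- function(groups, path) {
  rows <- lapply(groups, function(g) {
    stopifnot(inherits(g, "peak_group"))
    lip <- format_lipid(g$precursor)
    ms1 <- data.frame(sample_id = g$sample_id, lipid = lip,
                      transition_type = "MS1", isomer = "", fragment = "",
                      area = g$ms1_area, rt = g$rt, mobility = g$mobility)
    if (nrow(g$fragments) > 0L) {
      fr <- data.frame(sample_id = g$sample_id, lipid = lip,
                       transition_type = "fragment",
                       isomer = as.character(g$fragments$isomer),
                       fragment = as.character(g$fragments$fragment),
                       area = g$fragments$area, rt = g$rt,
                       mobility = g$mobility)
      fr <- fr[order(fr$isomer, fr$fragment), , drop = FALSE]
      rbind(ms1, fr)
    } else ms1
  })
  df <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(df)) df <- as.data.frame(stats::setNames(
    rep(list(character()), length(.REPORT_COLS)), .REPORT_COLS))
  df <- df[order(df$sample_id, df$lipid,
                 df$transition_type != "MS1", df$isomer, df$fragment), ,
           drop = FALSE]
  df$area <- sprintf("%.10g", as.numeric(df$area))
  df$rt <- ifelse(is.na(df$rt), "", sprintf("%.6g", as.numeric(df$rt)))
  df$mobility <- ifelse(is.na(df$mobility), "",
                        sprintf("%.6g", as.numeric(df$mobility)))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a tidy results table as TSV
#'
#' @param results a data frame (e.g. bound `sn_deconvolution` or
#'   `compositional_shares` rows).
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
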
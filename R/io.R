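## Tabular input/output -----------------------------------------------------
##
## All tables are tab-separated UTF-8 with a mandatory header row. Numeric
## parsing always uses the C decimal point, independent of the user locale.

#' Construct a validated %BOLD observation table
#'
#' A `bold_table` is a long-format data frame with one row per
#' (participant, contrast, ROI) observation of percent BOLD signal change.
#' Values are stored as percent (0.15 means 0.15%), the convention of
#' FSL-style ROI extraction tools; no rescaling is applied.
#'
#' @param participant,contrast character identifiers.
#' @param roi ROI labels, parsed with [parse_roi()].
#' @param value numeric %BOLD signal change; must be finite.
#' @return a data frame of class `bold_table` with columns
#'   `participant`, `contrast`, `roi`, `value`.
#' @export
bold_table <- function(participant, contrast, roi, value) {
  df <- data.frame(participant = as.character(participant),
                   contrast = as.character(contrast),
                   roi = parse_roi(roi),
                   value = value,
                   stringsAsFactors = FALSE)
  validate_bold_table(df)
}

validate_bold_table <- function(df) {
  if (!is.numeric(df$value)) {
    pbf_stop("non_numeric", "column 'value' must be numeric")
  }
  if (anyNA(df$value) || any(!is.finite(df$value))) {
    bad <- which(!is.finite(df$value))[1]
    pbf_stop("non_numeric",
             sprintf("non-finite %%BOLD value in row %d (%s, %s, %s)",
                     bad, df$participant[bad], df$contrast[bad], df$roi[bad]))
  }
  key <- paste(df$participant, df$contrast, df$roi, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[which(duplicated(key))[1], ]
    pbf_stop("duplicate_key",
             sprintf("duplicate observation for (%s, %s, %s)",
                     d$participant, d$contrast, d$roi))
  }
  class(df) <- c("bold_table", "data.frame")
  df
}

#' Read a %BOLD observation table
#'
#' @param path path to a tab-separated UTF-8 file with header columns
#'   `participant`, `contrast`, `roi`, `value`.
#' @return a [bold_table()].
#' @export
read_bold_table <- function(path) {
  df <- read_tsv_checked(path, c("participant", "contrast", "roi", "value"))
  num <- suppressWarnings(as.numeric(df$value))
  if (anyNA(num)) {
    bad <- df$value[which(is.na(num))[1]]
    pbf_stop("non_numeric", sprintf("non-numeric %%BOLD value '%s'", bad))
  }
  bold_table(df$participant, df$contrast, df$roi, num)
}

#' Read a contrast-to-condition assignment table
#'
#' Each fMRI contrast is assigned to exactly one behavioural condition:
#' `execution`, `inhibition_pro` (proactive/preparatory inhibition) or
#' `inhibition_reac` (reactive stopping). Repeated identical rows collapse;
#' a contrast listed with two different conditions is an error.
#'
#' @param path path to a TSV with header columns `contrast`, `condition`.
#' @return data frame of class `contrast_assignment` with columns
#'   `contrast`, `condition`.
#' @export
read_contrast_assignments <- function(path) {
  df <- read_tsv_checked(path, c("contrast", "condition"))
  contrast_assignment(df$contrast, df$condition)
}

#' Construct a contrast-to-condition assignment
#'
#' @param contrast character contrast identifiers.
#' @param condition one of `"execution"`, `"inhibition_pro"`,
#'   `"inhibition_reac"` per contrast.
#' @return data frame of class `contrast_assignment`.
#' @export
contrast_assignment <- function(contrast, condition) {
  contrast <- as.character(contrast)
  condition <- as.character(condition)
  bad <- setdiff(unique(condition), CONDITIONS)
  if (length(bad)) {
    pbf_stop("unknown_condition",
             sprintf("unknown condition label(s): %s (expected %s)",
                     paste(bad, collapse = ", "),
                     paste(CONDITIONS, collapse = ", ")))
  }
  df <- unique(data.frame(contrast = contrast, condition = condition,
                          stringsAsFactors = FALSE))
  if (anyDuplicated(df$contrast)) {
    c1 <- df$contrast[which(duplicated(df$contrast))[1]]
    pbf_stop("conflicting_assignment",
             sprintf("contrast '%s' is assigned to more than one condition", c1))
  }
  class(df) <- c("contrast_assignment", "data.frame")
  df
}

#' Write a statistics table as TSV
#'
#' Numeric columns are written at full double precision (15 significant
#' digits) and each additionally gets a 2-decimal `<name>_display` column
#' mirroring how such tables are conventionally printed. The file
#' round-trips through [read_stats_table()].
#'
#' @param records non-empty data frame.
#' @param path output path.
#' @param display add the 2-decimal display columns (default `TRUE`).
#' @return invisibly, the path written.
#' @export
write_stats_table <- function(records, path, display = TRUE) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) {
    pbf_stop("empty_records", "refusing to write an empty statistics table")
  }
  out <- records
  for (nm in names(records)) {
    if (is.numeric(records[[nm]])) {
      out[[nm]] <- sprintf("%.15g", records[[nm]])
      if (display) out[[paste0(nm, "_display")]] <- sprintf("%.2f", records[[nm]])
    }
  }
  ok <- tryCatch({
    suppressWarnings(
      write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                  fileEncoding = "UTF-8"))
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    pbf_stop("unwritable_path", sprintf("cannot write '%s': %s",
                                        path, conditionMessage(ok)))
  }
  invisible(path)
}

#' Read back a statistics table written by [write_stats_table()]
#'
#' Display columns (`*_display`) are dropped; columns that parse fully as
#' numbers are converted.
#'
#' @param path path to the TSV.
#' @return data frame.
#' @export
read_stats_table <- function(path) {
  df <- read_tsv_checked(path, character(0))
  df <- df[, !grepl("_display$", names(df)), drop = FALSE]
  for (nm in names(df)) {
    num <- suppressWarnings(as.numeric(df[[nm]]))
    if (!anyNA(num)) df[[nm]] <- num
  }
  df
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) {
    pbf_stop("missing_file", sprintf("file not found: '%s'", path))
  }
  df <- read.table(path, sep = "\t", header = TRUE, colClasses = "character",
                   check.names = FALSE, fileEncoding = "UTF-8",
                   comment.char = "", quote = "")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    pbf_stop("missing_column",
             sprintf("'%s' lacks required column(s): %s",
                     path, paste(missing, collapse = ", ")))
  }
  df
}
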
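#' Canonical 76-region AAL cortical dictionary
#'
#' Loads the ordered region-of-interest dictionary used throughout the
#' package: 76 cortical AAL regions (38 per hemisphere), each tagged with a
#' lobe (frontal, parietal, temporal, occipital, insula_cingulate). The
#' packaged default covers the standard AAL cortical labels; users may supply
#' their own table with the same three columns to override it.
#'
#' @param path Optional path to a tab-separated dictionary with columns
#'   `roi_name`, `hemisphere` (`L`/`R`) and `lobe`. When `NULL` the packaged
#'   dictionary is used.
#' @return A data frame with columns `roi_name`, `hemisphere`, `lobe` and
#'   `label` (`<roi_name>_<hemisphere>`), in canonical order.
#' @examples
#' dict <- roi_dictionary()
#' table(dict$lobe) / 2  # regions per lobe, per hemisphere
#' @export
roi_dictionary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "aal76_cortical_dictionary.tsv",
                        package = "cortexpls", mustWork = TRUE)
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("roi_name", "hemisphere", "lobe")
  if (!all(required %in% names(d))) {
    stop("dictionary must have columns: ", paste(required, collapse = ", "))
  }
  if (nrow(d) != 76L) {
    stop("dictionary must have exactly 76 entries, got ", nrow(d))
  }
  if (!all(d$hemisphere %in% c("L", "R")) ||
      any(table(d$hemisphere) != 38L)) {
    stop("dictionary must contain 38 'L' and 38 'R' entries")
  }
  d$label <- paste(d$roi_name, d$hemisphere, sep = "_")
  if (anyDuplicated(d$label)) stop("dictionary labels must be unique")
  valid_lobes <- c("frontal", "parietal", "temporal", "occipital",
                   "insula_cingulate")
  if (!all(d$lobe %in% valid_lobes)) {
    stop("unknown lobe label(s): ",
         paste(setdiff(d$lobe, valid_lobes), collapse = ", "))
  }
  d
}

#' Metrics measured in each cortical region
#'
#' Cortical thickness (CT, mm), surface area (SA, mm^2) and T1 relaxation
#' time (T1, ms).
#' @export
ROI_METRICS <- c("CT", "SA", "T1")

#' Participant group codes
#'
#' `CB` cisgender boys, `GD` gender-dysphoric adolescents assigned female at
#' birth, `CG` cisgender girls, in the canonical reporting order.
#' @export
GROUP_CODES <- c("CB", "GD", "CG")

## Months spanned by a 12-to-17-year-old cohort (ages rounded to the month,
## so the upper bound is one month past the 17th-year cutoff).
AGE_MONTHS_RANGE <- c(144L, 216L)

#' Validate a participant table
#'
#' Checks group codes, age range, questionnaire score ranges, and the rule
#' that derived EROS vector fields are absent whenever either raw EROS score
#' is missing.
#'
#' @param df Data frame with at least `participant_id`, `group`,
#'   `age_months`; optionally `gidyq_mean`, `eros_androphilia`,
#'   `eros_gynephilia`, `attraction_strength`, `attraction_phase_deg`.
#' @return The validated data frame (invisibly unchanged apart from group
#'   being made a factor with canonical level order).
#' @export
validate_participants <- function(df) {
  required <- c("participant_id", "group", "age_months")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("participant table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  bad_group <- which(!(as.character(df$group) %in% GROUP_CODES))
  if (length(bad_group) > 0L) {
    stop("unknown group code '", as.character(df$group)[bad_group[1L]],
         "' in row ", bad_group[1L], " (expected CB, GD or CG)")
  }
  df$group <- factor(as.character(df$group), levels = GROUP_CODES)
  if (!is.numeric(df$age_months) || anyNA(df$age_months)) {
    stop("age_months must be numeric and complete")
  }
  if (any(df$age_months < AGE_MONTHS_RANGE[1L] |
          df$age_months > AGE_MONTHS_RANGE[2L])) {
    stop("age_months outside the 12-17 year window [",
         AGE_MONTHS_RANGE[1L], ", ", AGE_MONTHS_RANGE[2L], "] months")
  }
  for (col in c("gidyq_mean", "eros_androphilia", "eros_gynephilia")) {
    if (col %in% names(df)) {
      v <- df[[col]]
      if (any(!is.na(v) & (v < 1 | v > 5))) {
        stop(col, " must lie in [1, 5]")
      }
    }
  }
  eros_missing <- rep(FALSE, nrow(df))
  if (all(c("eros_androphilia", "eros_gynephilia") %in% names(df))) {
    eros_missing <- is.na(df$eros_androphilia) | is.na(df$eros_gynephilia)
  }
  for (col in c("attraction_strength", "attraction_phase_deg")) {
    if (col %in% names(df) && any(eros_missing & !is.na(df[[col]]))) {
      stop(col, " must be missing whenever either EROS score is missing")
    }
  }
  if (anyDuplicated(df$participant_id)) {
    stop("participant_id values must be unique")
  }
  df
}

#' Read a participant table from CSV
#'
#' @param path Path to a comma-separated file with a header row. Empty cells
#'   encode missing values; the `group` column must use the codes `CB`,
#'   `GD`, `CG`.
#' @return A validated data frame of participants (one row each). Columns
#'   beyond the recognised ones are preserved untouched.
#' @export
read_participant_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_participants(df)
}

#' Write a participant table to CSV
#'
#' Inverse of [read_participant_table()]; numeric fields are written at full
#' precision and missing values as empty cells.
#' @param df Participant data frame.
#' @param path Output path.
#' @export
write_participant_table <- function(df, path) {
  utils::write.csv(format_full_precision(df), path, row.names = FALSE,
                   na = "", quote = FALSE)
  invisible(path)
}

## Render doubles with enough digits (%.17g) that read-back is bit-exact.
format_full_precision <- function(df) {
  for (col in names(df)) {
    if (is.double(df[[col]])) {
      v <- sprintf("%.17g", df[[col]])
      v[is.na(df[[col]])] <- NA_character_
      df[[col]] <- v
    }
  }
  df
}

#' Construct an ROI matrix
#'
#' A participants-by-columns numeric matrix holding cortical thickness (mm),
#' surface area (mm^2) and T1 (ms) for each dictionary region, with columns
#' in canonical order: all CT columns in dictionary order, then SA, then T1.
#'
#' @param values Numeric matrix, rows = participants.
#' @param column_index Data frame with columns `label`, `roi_name`,
#'   `hemisphere`, `lobe`, `metric` describing each column of `values`.
#' @param is_zscored Logical flag; when `TRUE` every column must have mean 0
#'   and unit (n-1) standard deviation.
#' @return An object of class `roi_matrix`.
#' @export
roi_matrix <- function(values, column_index, is_zscored = FALSE) {
  values <- as.matrix(values)
  if (ncol(values) != nrow(column_index)) {
    stop("column_index must describe every column of values")
  }
  if (anyNA(values)) stop("ROI matrix must not contain missing values")
  colnames(values) <- paste(column_index$label, column_index$metric,
                            sep = "_")
  x <- structure(
    list(values = values, column_index = column_index,
         is_zscored = isTRUE(is_zscored)),
    class = "roi_matrix")
  if (x$is_zscored) stopifnot(all(abs(colMeans(values)) < 1e-8))
  x
}

#' @export
print.roi_matrix <- function(x, ...) {
  cat(sprintf("<roi_matrix> %d participants x %d columns (%s)%s\n",
              nrow(x$values), ncol(x$values),
              paste(unique(x$column_index$metric), collapse = "/"),
              if (x$is_zscored) ", z-scored" else ""))
  invisible(x)
}

#' @export
dim.roi_matrix <- function(x) dim(x$values)

## Canonical column order: metric-major (CT, SA, T1), dictionary order
## within each metric block.
canonical_column_index <- function(dictionary,
                                   metrics = ROI_METRICS) {
  blocks <- lapply(metrics, function(m) {
    data.frame(label = dictionary$label,
               roi_name = dictionary$roi_name,
               hemisphere = dictionary$hemisphere,
               lobe = dictionary$lobe,
               metric = m,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, blocks)
}

#' Read a wide ROI table into canonical form
#'
#' Reads a CSV/TSV with one row per participant, a `participant_id` column,
#' and one column per region-metric pair named `<roi>_<hemisphere>_<metric>`
#' (e.g. `Insula_L_SA`). Columns are reordered to canonical dictionary
#' order, so tables with shuffled columns load identically.
#'
#' @param path Path to the table; `.tsv` extension selects tab separation.
#' @param dictionary Dictionary from [roi_dictionary()].
#' @param metrics Metrics expected (default all of CT, SA, T1).
#' @param header_map Optional path to a two-column CSV (`from`, `to`)
#'   renaming foreign column headers to the canonical
#'   `<roi>_<hemisphere>_<metric>` dialect, so archived tables with a
#'   different naming scheme load without code changes.
#' @return An `roi_matrix` with participant ids as row names.
#' @export
read_roi_matrix <- function(path, dictionary = roi_dictionary(),
                            metrics = ROI_METRICS, header_map = NULL) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(header_map)) {
    hm <- utils::read.csv(header_map, stringsAsFactors = FALSE)
    stopifnot(all(c("from", "to") %in% names(hm)))
    hit <- match(names(df), hm$from)
    names(df)[!is.na(hit)] <- hm$to[hit[!is.na(hit)]]
  }
  if (!"participant_id" %in% names(df)) {
    stop("ROI table must have a participant_id column")
  }
  idx <- canonical_column_index(dictionary, metrics)
  wanted <- paste(idx$label, idx$metric, sep = "_")
  missing_cols <- setdiff(wanted, names(df))
  if (length(missing_cols) > 0L) {
    stop("ROI table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  values <- as.matrix(df[, wanted])
  if (!is.numeric(values)) stop("ROI columns must be numeric")
  if (anyNA(values)) {
    bad <- which(apply(is.na(values), 2, any))
    stop("ROI table has missing values in column(s): ",
         paste(wanted[bad], collapse = ", "))
  }
  rownames(values) <- df$participant_id
  roi_matrix(values, idx, is_zscored = FALSE)
}

#' Write an ROI matrix as a wide CSV
#'
#' @param x An `roi_matrix`.
#' @param path Output path (CSV).
#' @export
write_roi_matrix <- function(x, path) {
  df <- data.frame(participant_id = rownames(x$values),
                   x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(format_full_precision(df), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
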
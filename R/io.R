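# CSV reading and writing -----------------------------------------------------
#
# Record CSV schema: columns record_id, taxon, species, carcass_code, the five
# ordinal score columns and the three system-set columns. System-set cells are
# semicolon-separated system tokens, with "none" for an assessed-but-clear
# examination; an empty cell means the parameter was not assessed. Empty
# ordinal cells likewise mean not assessed. Unknown extra columns are ignored.

parse_set_cell <- function(cell) {
  if (is.na(cell) || trimws(cell) == "") {
    return(NA_character_)
  }
  if (trimws(cell) == "none") {
    return(character(0))
  }
  trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
}

format_set_cell <- function(set) {
  if (is_missing_set(set)) {
    ""
  } else if (length(set) == 0L) {
    "none"
  } else {
    paste(set, collapse = ";")
  }
}

#' Read necropsy records from CSV
#'
#' Parses and validates a record CSV (see [write_records()] for the schema).
#' Malformed rows — non-numeric or out-of-range scores, unknown taxon or
#' system tokens, duplicated systems — are rejected with row-level
#' diagnostics, never silently coerced. Missing (empty) cells are legal and
#' simply make the record's HI indeterminable. With `filter_fresh = TRUE`
#' records whose carcass code is not 2 ("fresh") are dropped, the condition
#' under which cohort analyses are defined: decomposed carcasses rarely
#' allow all eight parameters to be assessed.
#'
#' @param path CSV file path.
#' @param filter_fresh Drop records with `carcass_code != 2` (default TRUE).
#' @return A list with `records` (validated record tibble), `rejected`
#'   (tibble of findings for rejected rows), and the bookkeeping counts
#'   `n_read`, `n_rejected`, `n_filtered_not_fresh`, `n_kept`
#'   (`n_read = n_kept + n_rejected + n_filtered_not_fresh`).
#' @export
read_records <- function(path, filter_fresh = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing_cols <- setdiff(record_columns(), names(raw))
  if (length(missing_cols) > 0) {
    stop(
      "CSV is missing mandatory column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  n_read <- nrow(raw)

  parse_ord <- function(x) {
    out <- rep(NA_integer_, length(x))
    has <- !is.na(x) & trimws(x) != ""
    suppressWarnings(v <- as.numeric(x[has]))
    out[has] <- ifelse(is.na(v) | v != trunc(v), NA_integer_, as.integer(v))
    bad <- has & is.na(out)
    list(value = out, bad = bad)
  }

  ord_cols <- setdiff(unname(param_columns()), set_parameters())
  parsed <- tibble::tibble(
    record_id = raw$record_id,
    taxon = raw$taxon,
    species = raw$species
  )
  bad_numeric <- tibble::tibble(
    row = integer(), record_id = character(), class = character(),
    field = character(), message = character()
  )
  cc <- parse_ord(raw$carcass_code) # reuse integer parsing; range not checked
  parsed$carcass_code <- cc$value
  for (col in ord_cols) {
    p <- parse_ord(raw[[col]])
    parsed[[col]] <- p$value
    if (any(p$bad)) {
      bad_numeric <- dplyr::bind_rows(bad_numeric, tibble::tibble(
        row = which(p$bad), record_id = raw$record_id[p$bad],
        class = "not_a_score", field = col,
        message = paste0("cell '", raw[[col]][p$bad], "' is not an integer score")
      ))
    }
  }
  for (col in set_parameters()) {
    parsed[[col]] <- lapply(raw[[col]], parse_set_cell)
  }
  parsed <- parsed[, record_columns()]

  findings <- dplyr::bind_rows(validate_records(parsed), bad_numeric)
  fatal <- findings[findings$class != "missing", , drop = FALSE]
  bad_rows <- sort(unique(fatal$row))
  records <- parsed[setdiff(seq_len(n_read), bad_rows), , drop = FALSE]

  n_filtered <- 0L
  if (filter_fresh) {
    fresh <- !is.na(records$carcass_code) & records$carcass_code == 2L
    n_filtered <- sum(!fresh)
    records <- records[fresh, , drop = FALSE]
  }
  list(
    records = records,
    rejected = fatal,
    n_read = n_read,
    n_rejected = length(bad_rows),
    n_filtered_not_fresh = n_filtered,
    n_kept = nrow(records)
  )
}

#' Write necropsy records to CSV
#'
#' Inverse of [read_records()]: system sets are serialized as
#' semicolon-joined tokens ("none" for an assessed empty set, empty cell for
#' not assessed); unassessed scores become empty cells.
#'
#' @param records A record tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  check_records_frame(records)
  out <- records
  for (col in set_parameters()) {
    out[[col]] <- vapply(records[[col]], format_set_cell, character(1))
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Write HI results to CSV
#'
#' Serializes a [compute_hi()] result table. HI values are rounded to four
#' decimal places; indeterminable records carry the literal `NA` in the
#' `hi` column and their missing parameter names in `missing_parameters`.
#'
#' @param results A result tibble from [compute_hi()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_hi_results <- function(results, path) {
  out <- results
  out$hi <- round(out$hi, 4)
  readr::write_csv(out, path, na = "NA")
  invisible(path)
}

#' Read HI results written by [write_hi_results()]
#'
#' @param path CSV path.
#' @return A tibble; `hi` is numeric with NA for indeterminable records.
#' @export
read_hi_results <- function(path) {
  readr::read_csv(path,
    col_types = readr::cols(
      record_id = readr::col_character(),
      taxon = readr::col_character(),
      missing_parameters = readr::col_character(),
      determinable = readr::col_logical(),
      .default = readr::col_double()
    ),
    na = "NA", progress = FALSE
  )
}

#' Loose reader for external HI-value tables
#'
#' Ingests any CSV containing a column of HI values plus an optional
#' grouping column (taxon, species, ...), for benchmarking cohort summaries
#' against externally published per-animal HI tables whose exact layout is
#' not fixed.
#'
#' @param path CSV path.
#' @param hi_col Name of the HI column (default `"hi"`).
#' @param group_col Optional name of a grouping column.
#' @return A tibble with columns `hi` and, if requested, `group`; rows with
#'   missing HI are dropped, out-of-range values are an error.
#' @export
read_hi_table <- function(path, hi_col = "hi", group_col = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (!hi_col %in% names(raw)) {
    stop("no column '", hi_col, "' in ", path, call. = FALSE)
  }
  hi <- suppressWarnings(as.numeric(raw[[hi_col]]))
  out <- tibble::tibble(hi = hi)
  if (!is.null(group_col)) {
    if (!group_col %in% names(raw)) {
      stop("no column '", group_col, "' in ", path, call. = FALSE)
    }
    out$group <- raw[[group_col]]
  }
  out <- out[!is.na(out$hi), , drop = FALSE]
  if (any(out$hi < 0 | out$hi > 1)) {
    stop("HI values outside [0, 1] in ", path, call. = FALSE)
  }
  out
}
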
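# Necropsy record data frame -------------------------------------------------

record_columns <- function() {
  c(
    "record_id", "taxon", "species", "carcass_code",
    "body_score", "systems_macro", "cutaneous_score", "systems_organized",
    "systems_histo", "parasitosis_score", "lymphoid_depletion_score",
    "thyroid_score"
  )
}

# a system-set cell is "missing" (not assessed) when it is NULL or a single NA;
# an assessed-but-clear organ check is the empty character vector
is_missing_set <- function(x) {
  is.null(x) || (length(x) == 1L && is.na(x))
}

#' Build a single necropsy record
#'
#' Convenience constructor producing a one-row record tibble in the schema
#' used throughout the package. Ordinal scores are integers 0-3 (`NA` =
#' parameter not assessed). System sets are character vectors of organ-system
#' labels from [hi_systems()]; `character(0)` means the systems were examined
#' and none affected, while `NA` means the parameter was not assessed.
#'
#' @param record_id Identifier string.
#' @param taxon One of [hi_taxa()].
#' @param species Free-text species name.
#' @param carcass_code Decomposition code; 2 = fresh, the only state used in
#'   cohort analyses. Carried on the record but ignored by scoring.
#' @param body_score,cutaneous_score,parasitosis_score,lymphoid_depletion_score,thyroid_score
#'   Ordinal 0-3 or `NA`.
#' @param systems_macro,systems_organized,systems_histo Character vectors of
#'   affected organ systems (macroscopic, organized/old lesions,
#'   histopathology), `character(0)` for none, `NA` for not assessed.
#' @return A one-row tibble; bind rows of these to form a cohort.
#' @examples
#' necropsy_record("A1", "seabird",
#'   body_score = 1,
#'   systems_macro = c("respiratory", "digestive")
#' )
#' @export
necropsy_record <- function(record_id, taxon, species = NA_character_,
                            carcass_code = 2L,
                            body_score = NA_integer_,
                            systems_macro = NA,
                            cutaneous_score = NA_integer_,
                            systems_organized = NA,
                            systems_histo = NA,
                            parasitosis_score = NA_integer_,
                            lymphoid_depletion_score = NA_integer_,
                            thyroid_score = NA_integer_) {
  as_ord <- function(x) {
    if (length(x) != 1L) stop("ordinal scores must be length 1", call. = FALSE)
    if (is.na(x)) NA_integer_ else as.integer(x)
  }
  tibble::tibble(
    record_id = as.character(record_id),
    taxon = as.character(taxon),
    species = as.character(species),
    carcass_code = as.integer(carcass_code),
    body_score = as_ord(body_score),
    systems_macro = list(norm_set(systems_macro)),
    cutaneous_score = as_ord(cutaneous_score),
    systems_organized = list(norm_set(systems_organized)),
    systems_histo = list(norm_set(systems_histo)),
    parasitosis_score = as_ord(parasitosis_score),
    lymphoid_depletion_score = as_ord(lymphoid_depletion_score),
    thyroid_score = as_ord(thyroid_score)
  )
}

norm_set <- function(x) {
  if (is_missing_set(x)) NA_character_ else as.character(x)
}

check_records_frame <- function(records) {
  if (!is.data.frame(records)) {
    stop("`records` must be a data frame of necropsy records", call. = FALSE)
  }
  missing_cols <- setdiff(record_columns(), names(records))
  if (length(missing_cols) > 0) {
    stop(
      "records are missing mandatory column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  invisible(records)
}

#' Validate necropsy records
#'
#' Checks every record against the data contract: ordinal scores in
#' \{0, 1, 2, 3\}, system sets drawn from the ten known organ systems with
#' no duplicates, and a known taxon. Parameters that were not assessed are
#' reported as findings of class `"missing"`; they are not format errors,
#' but any record with a missing parameter has an indeterminable HI.
#'
#' @param records A record tibble (see [necropsy_record()]).
#' @return A tibble of findings with columns `row`, `record_id`, `class`
#'   (`"ordinal_out_of_range"`, `"unknown_system"`, `"duplicate_system"`,
#'   `"unknown_taxon"` or `"missing"`), `field` and `message`. Zero rows for
#'   a fully well-formed, complete cohort.
#' @examples
#' rec <- necropsy_record("A1", "seabird", body_score = 5)
#' validate_records(rec)
#' @export
validate_records <- function(records) {
  check_records_frame(records)
  cols <- param_columns()
  out <- list()
  add <- function(row, id, class, field, msg) {
    out[[length(out) + 1L]] <<- tibble::tibble(
      row = row, record_id = id, class = class, field = field, message = msg
    )
  }
  known <- names(hi_systems())
  for (i in seq_len(nrow(records))) {
    id <- records$record_id[i]
    tx <- records$taxon[i]
    if (is.na(tx) || !tx %in% hi_taxa()) {
      add(i, id, "unknown_taxon", "taxon", paste0("unknown taxon '", tx, "'"))
    }
    for (p in hi_parameters()) {
      col <- cols[[p]]
      if (p %in% set_parameters()) {
        val <- records[[col]][[i]]
        if (is_missing_set(val)) {
          add(i, id, "missing", p, paste0("parameter '", p, "' not assessed"))
        } else {
          bad <- setdiff(val, known)
          if (length(bad) > 0) {
            add(
              i, id, "unknown_system", p,
              paste0("unknown system token(s): ", paste(bad, collapse = ", "))
            )
          }
          if (anyDuplicated(val) > 0) {
            add(
              i, id, "duplicate_system", p,
              paste0(
                "duplicated system(s): ",
                paste(unique(val[duplicated(val)]), collapse = ", ")
              )
            )
          }
        }
      } else {
        val <- records[[col]][i]
        if (is.na(val)) {
          add(i, id, "missing", p, paste0("parameter '", p, "' not assessed"))
        } else if (!val %in% 0:3) {
          add(
            i, id, "ordinal_out_of_range", p,
            paste0("score ", val, " outside 0-3")
          )
        }
      }
    }
  }
  if (length(out) == 0) {
    tibble::tibble(
      row = integer(), record_id = character(), class = character(),
      field = character(), message = character()
    )
  } else {
    dplyr::bind_rows(out)
  }
}
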
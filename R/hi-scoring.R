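# Health Index scoring --------------------------------------------------------

#' Ordinal score from a count of affected organ systems
#'
#' The three system-count parameters (systemic conditions at macroscopy and
#' histopathology, organized lesions) convert the number of affected systems
#' to an ordinal score: 0 for no affected systems, 1 for 1-3, 2 for 4-6,
#' 3 for more than 6.
#'
#' @param n_systems Non-negative integer vector of counts, at most 10 (the
#'   number of defined organ systems).
#' @return Integer vector of scores 0-3.
#' @examples
#' systemic_score_from_count(c(0, 3, 4, 7))
#' @export
systemic_score_from_count <- function(n_systems) {
  if (any(is.na(n_systems)) ||
    any(n_systems < 0 | n_systems > 10 | n_systems != trunc(n_systems))) {
    stop("`n_systems` must be whole numbers between 0 and 10", call. = FALSE)
  }
  findInterval(n_systems, c(1, 4, 7))
}

#' Weight applicable to a set of affected organ systems
#'
#' When a system-count parameter involves several systems, the highest
#' weight class among them applies: e.g. lesions in the respiratory,
#' digestive and nervous systems carry weight 3 because the nervous system
#' is affected. The empty set returns 1 by convention; its score is 0, so
#' the weight never contributes.
#'
#' @param systems A character vector of organ-system labels, or a list of
#'   such vectors.
#' @return Integer weight(s) in 1-3.
#' @examples
#' weight_for_systems(c("respiratory", "digestive", "nervous"))
#' weight_for_systems(list(character(0), "reproductive"))
#' @export
weight_for_systems <- function(systems) {
  if (!is.list(systems)) {
    return(weight_for_systems(list(systems))[[1L]])
  }
  w <- hi_systems()
  vapply(systems, function(s) {
    if (is_missing_set(s)) {
      return(NA_integer_)
    }
    bad <- setdiff(s, names(w))
    if (length(bad) > 0) {
      stop(
        "unknown system label(s): ", paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    if (length(s) == 0L) 1L else max(w[s])
  }, integer(1))
}

#' Compute the Health Index for necropsy records
#'
#' For each record, every parameter's value is its score times its weight
#' (`value = score x weight`); the Health Index is
#' `HI = 1 - sum(values) / HImax`, where `HImax` is the taxon-specific
#' maximum raw sum, so 1 marks a healthy animal and 0 one with every
#' parameter at its worst. System-count parameters take their score from
#' [systemic_score_from_count()] and their weight from the highest affected
#' system ([weight_for_systems()]); the organized-lesions weight follows the
#' scheme variant; the remaining parameters carry fixed weights, except the
#' body score whose weight is taxon-specific.
#'
#' A record with any unassessed parameter is marked `determinable = FALSE`
#' and gets no numeric HI — a partial sum would artificially inflate the
#' apparent health of the animal.
#'
#' @param records A record tibble (see [necropsy_record()], [read_records()],
#'   [simulate_cohort()]). Must be format-valid; format violations (bad
#'   ordinals, unknown systems or taxa) are an error. Missing parameters are
#'   allowed and yield indeterminable results.
#' @param scheme An [scoring_scheme()] object.
#' @return A tibble with one row per record: `record_id`, `taxon`, one
#'   `value_<parameter>` column per parameter (NA when that parameter is
#'   missing), `raw_sum`, `hi_max`, `hi` (NA when indeterminable),
#'   `determinable`, and `missing_parameters` (semicolon-joined names, ""
#'   when complete).
#' @examples
#' rec <- necropsy_record("A1", "seabird",
#'   body_score = 0, systems_macro = c("respiratory", "digestive", "nervous"),
#'   cutaneous_score = 0, systems_organized = character(0),
#'   systems_histo = character(0), parasitosis_score = 0,
#'   lymphoid_depletion_score = 0, thyroid_score = 0
#' )
#' compute_hi(rec)$hi # 1 - 3/48
#' @export
compute_hi <- function(records, scheme = scoring_scheme()) {
  check_records_frame(records)
  findings <- validate_records(records)
  fatal <- findings[findings$class != "missing", , drop = FALSE]
  if (nrow(fatal) > 0) {
    stop(
      "records contain format errors (run validate_records() for details): ",
      paste(head(fatal$message, 3L), collapse = "; "),
      if (nrow(fatal) > 3) " ...",
      call. = FALSE
    )
  }

  n <- nrow(records)
  w_sys <- hi_systems()

  set_value <- function(col, use_system_weights) {
    sets <- records[[col]]
    vapply(sets, function(s) {
      if (is_missing_set(s)) {
        return(NA_real_)
      }
      score <- systemic_score_from_count(length(s))
      weight <- if (!use_system_weights) {
        1L
      } else if (length(s) == 0L) 1L else max(w_sys[s])
      as.numeric(score * weight)
    }, numeric(1))
  }

  body_w <- unname(scheme$body_weight[records$taxon])
  fixed <- scheme$fixed_weights
  values <- tibble::tibble(
    value_body = as.numeric(records$body_score * body_w),
    value_systems_macro = set_value("systems_macro", TRUE),
    value_cutaneous = as.numeric(records$cutaneous_score * fixed[["cutaneous"]]),
    value_systems_organized = set_value(
      "systems_organized", scheme$organized_uses_system_weights
    ),
    value_systems_histo = set_value("systems_histo", TRUE),
    value_parasitosis = as.numeric(
      records$parasitosis_score * fixed[["parasitosis"]]
    ),
    value_lymphoid_depletion = as.numeric(
      records$lymphoid_depletion_score * fixed[["lymphoid_depletion"]]
    ),
    value_thyroid = as.numeric(records$thyroid_score * fixed[["thyroid"]])
  )

  vm <- as.matrix(values)
  missing_mask <- is.na(vm)
  determinable <- rowSums(missing_mask) == 0L
  raw_sum <- ifelse(determinable, rowSums(vm, na.rm = TRUE), NA_real_)
  himax <- hi_max(records$taxon, scheme)
  hi <- ifelse(determinable, 1 - raw_sum / himax, NA_real_)

  missing_parameters <- vapply(seq_len(n), function(i) {
    paste(hi_parameters()[missing_mask[i, ]], collapse = ";")
  }, character(1))

  dplyr::bind_cols(
    tibble::tibble(record_id = records$record_id, taxon = records$taxon),
    values,
    tibble::tibble(
      raw_sum = raw_sum, hi_max = himax, hi = hi,
      determinable = determinable, missing_parameters = missing_parameters
    )
  )
}
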
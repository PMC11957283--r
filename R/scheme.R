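# Controlled vocabulary ------------------------------------------------------

#' Taxa, organ systems and parameters recognised by the Health Index
#'
#' The Health Index (HI) is defined for three taxa of stranded marine
#' tetrapods. Lesion-bearing organ systems are drawn from the ten systems of
#' standard necropsy protocols, each carrying a weight class 1-3 reflecting
#' its importance for short-term homeostasis. Eight parameters contribute to
#' the index: four macroscopic (body score, systemic conditions, cutaneous
#' injuries, organized lesions) and four histopathological (systemic
#' conditions, parasitosis, lymphoid depletion, thyroid alterations).
#'
#' @format
#' * `hi_taxa()`: character vector of the three taxon labels.
#' * `hi_systems()`: named integer vector mapping each of the ten organ
#'   systems to its weight class (1, 2 or 3).
#' * `hi_parameters()`: character vector of the eight parameter names, in
#'   canonical order.
#'
#' @details The weight classes are: 1 for reproductive, musculoskeletal and
#' lympho-hematopoietic systems; 2 for digestive, respiratory and urinary;
#' 3 for nervous, endocrine and cardiovascular. The integumentary system
#' carries weight 1: skin lesions already have a dedicated parameter
#' (cutaneous injuries), so integumentary involvement counts toward system
#' tallies at the lowest weight.
#'
#' @return See Format.
#' @examples
#' hi_taxa()
#' hi_systems()
#' @export
hi_taxa <- function() c("seabird", "marine_mammal", "sea_turtle")

#' @rdname hi_taxa
#' @export
hi_systems <- function() {
  c(
    integumentary = 1L, cardiovascular = 3L, nervous = 3L,
    respiratory = 2L, digestive = 2L, urinary = 2L,
    lympho_hematopoietic = 1L, endocrine = 3L,
    musculoskeletal = 1L, reproductive = 1L
  )
}

#' @rdname hi_taxa
#' @export
hi_parameters <- function() {
  c(
    "body", "systems_macro", "cutaneous", "systems_organized",
    "systems_histo", "parasitosis", "lymphoid_depletion", "thyroid"
  )
}

# columns of the record data frame holding each parameter's raw observation
param_columns <- function() {
  c(
    body = "body_score",
    systems_macro = "systems_macro",
    cutaneous = "cutaneous_score",
    systems_organized = "systems_organized",
    systems_histo = "systems_histo",
    parasitosis = "parasitosis_score",
    lymphoid_depletion = "lymphoid_depletion_score",
    thyroid = "thyroid_score"
  )
}

set_parameters <- function() c("systems_macro", "systems_organized", "systems_histo")

# Scoring scheme --------------------------------------------------------------

#' Construct a Health Index scoring scheme
#'
#' A scheme bundles the parameter weights and the taxon-specific maximum raw
#' sum (`HImax`) that normalises the index. Two variants are supported:
#'
#' * `"paper"` (default): the organized-lesions parameter, which like the
#'   two systemic-conditions parameters is scored from a count of affected
#'   systems, also takes the system-dependent weight (1-3, highest affected
#'   system). This yields HImax 48 for seabirds and marine mammals and 51
#'   for sea turtles, the maxima the index was standardised against.
#' * `"literal"`: organized lesions keep a fixed weight of 1, the weight
#'   printed beneath that parameter's definition; maxima become 42 and 45.
#'
#' The body score is the only parameter whose weight differs by taxon:
#' 1 for the endotherms (seabirds, marine mammals), whose body condition
#' responds quickly to ill health, and 2 for sea turtles, whose slower
#' ectotherm metabolism makes a poor body score a weightier finding.
#'
#' @param variant `"paper"` or `"literal"`.
#' @return An object of class `hi_scheme`: a list with elements `variant`,
#'   `body_weight` (named integer vector over taxa), `fixed_weights`
#'   (cutaneous, parasitosis, lymphoid_depletion, thyroid) and
#'   `organized_uses_system_weights` (logical).
#' @examples
#' scoring_scheme()
#' hi_max("sea_turtle", scoring_scheme("literal"))
#' @export
scoring_scheme <- function(variant = c("paper", "literal")) {
  variant <- match.arg(variant)
  structure(
    list(
      variant = variant,
      body_weight = c(seabird = 1L, marine_mammal = 1L, sea_turtle = 2L),
      fixed_weights = c(
        cutaneous = 1L, parasitosis = 1L,
        lymphoid_depletion = 2L, thyroid = 2L
      ),
      organized_uses_system_weights = variant == "paper"
    ),
    class = "hi_scheme"
  )
}

#' @export
print.hi_scheme <- function(x, ...) {
  cat("<hi_scheme> variant:", x$variant, "\n")
  cat("  body weight: seabird/marine_mammal 1, sea_turtle 2\n")
  cat(
    "  organized lesions weight:",
    if (x$organized_uses_system_weights) "system-dependent (1-3)" else "fixed 1", "\n"
  )
  cat(
    "  HImax: seabird/marine_mammal", hi_max("seabird", x),
    "| sea_turtle", hi_max("sea_turtle", x), "\n"
  )
  invisible(x)
}

# maximum weight each parameter can take under a scheme, for one taxon
max_weights <- function(taxon, scheme) {
  stopifnot(inherits(scheme, "hi_scheme"))
  w_sys_max <- max(hi_systems())
  c(
    body = unname(scheme$body_weight[taxon]),
    systems_macro = w_sys_max,
    cutaneous = scheme$fixed_weights[["cutaneous"]],
    systems_organized = if (scheme$organized_uses_system_weights) w_sys_max else 1L,
    systems_histo = w_sys_max,
    parasitosis = scheme$fixed_weights[["parasitosis"]],
    lymphoid_depletion = scheme$fixed_weights[["lymphoid_depletion"]],
    thyroid = scheme$fixed_weights[["thyroid"]]
  )
}

#' Maximum achievable raw parameter sum (HImax) for a taxon
#'
#' The HI denominator: the raw weighted sum of a hypothetical worst-case
#' record, i.e. every parameter at score 3 with its maximum applicable
#' weight. Under the default scheme this is 48 for seabirds and marine
#' mammals and 51 for sea turtles.
#'
#' @param taxon Character vector of taxon labels (see [hi_taxa()]).
#' @param scheme An [scoring_scheme()] object.
#' @return Integer vector of maxima, one per input taxon.
#' @examples
#' hi_max(c("seabird", "sea_turtle"))
#' @export
hi_max <- function(taxon, scheme = scoring_scheme()) {
  check_taxon(taxon)
  vapply(taxon, function(t) sum(3L * max_weights(t, scheme)), integer(1),
    USE.NAMES = FALSE
  )
}

check_taxon <- function(taxon) {
  bad <- setdiff(unique(taxon[!is.na(taxon)]), hi_taxa())
  if (length(bad) > 0) {
    stop(
      "unknown taxon label(s): ", paste(bad, collapse = ", "),
      "; expected one of ", paste(hi_taxa(), collapse = ", "),
      call. = FALSE
    )
  }
  invisible(taxon)
}
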
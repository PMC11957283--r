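# Synthetic necropsy cohorts --------------------------------------------------

#' Configuration for the synthetic cohort generator
#'
#' The generator draws a latent morbidity `m` in [0, 1] per animal from a
#' Beta distribution and derives every observable from it: ordinal scores
#' via a cumulative-threshold model with a small perturbation probability,
#' affected-system sets by including each organ system independently with a
#' probability increasing in `m`, and a subjective veterinarian rating
#' ("good"/"fair"/"poor") by thresholding `m` with a misclassification
#' probability emulating inter-rater disagreement.
#'
#' Defaults emulate the broad features of fresh-carcass stranding cohorts:
#' right-skewed morbidity (`Beta(2, 5)`) so most animals are in fair-to-good
#' condition, HI mean near 0.7, and a negatively skewed HI distribution.
#'
#' @param n_animals Number of records to generate.
#' @param taxon_mix Named proportions over `seabird`, `marine_mammal`,
#'   `sea_turtle`; must sum to 1. Default mirrors a seabird-dominated
#'   stranding cohort with a large turtle fraction.
#' @param shape_a,shape_b Beta shape parameters of the latent morbidity.
#' @param ordinal_thresholds Three increasing cutpoints in (0, 1) mapping
#'   `m` to ordinal scores 0-3, applied to all five directly scored ordinal
#'   parameters; alternatively a named list giving per-parameter cutpoints
#'   (names among `body`, `cutaneous`, `parasitosis`, `lymphoid_depletion`,
#'   `thyroid`).
#' @param ordinal_noise Probability that an ordinal score is shifted one
#'   category up or down (clamped to 0-3).
#' @param system_scale Slope of the per-system inclusion probability
#'   `p = min(1, scale * m)` for the macroscopic and histopathological
#'   system sets.
#' @param organized_scale Same, for the organized-lesions set; old resolved
#'   lesions are rarer, so the default is lower.
#' @param weight3_factor Multiplier (0-1] applied to the inclusion
#'   probability of the weight-3 systems (nervous, endocrine,
#'   cardiovascular), which are less commonly compromised than e.g. the
#'   digestive tract in stranded animals.
#' @param vet_cutpoints Two increasing cutpoints on `m` separating
#'   good/fair/poor ratings.
#' @param vet_noise Probability that a rating moves to an adjacent category.
#' @param missing_rate Probability that any given parameter is unassessed
#'   (0 = complete records).
#' @param seed Integer seed; a config fully determines its cohort.
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' sim_config(n_animals = 50, seed = 7)
#' @export
sim_config <- function(n_animals = 2000,
                       taxon_mix = c(seabird = 0.60, marine_mammal = 0.05, sea_turtle = 0.35),
                       shape_a = 2, shape_b = 5,
                       ordinal_thresholds = c(0.15, 0.45, 0.75),
                       ordinal_noise = 0.05,
                       system_scale = 1.0,
                       organized_scale = 0.6,
                       weight3_factor = 0.6,
                       vet_cutpoints = c(0.25, 0.50),
                       vet_noise = 0.10,
                       missing_rate = 0,
                       seed = 1L) {
  if (n_animals < 1) stop("`n_animals` must be positive", call. = FALSE)
  if (!setequal(names(taxon_mix), hi_taxa())) {
    stop("`taxon_mix` must be named over ", paste(hi_taxa(), collapse = ", "),
      call. = FALSE
    )
  }
  if (abs(sum(taxon_mix) - 1) > 1e-8 || any(taxon_mix < 0)) {
    stop("`taxon_mix` proportions must be non-negative and sum to 1", call. = FALSE)
  }
  if (shape_a <= 0 || shape_b <= 0) stop("Beta shapes must be positive", call. = FALSE)
  thr <- ordinal_thresholds
  if (!is.list(thr)) thr <- stats::setNames(rep(list(thr), 5), ordinal_parameters())
  for (p in ordinal_parameters()) {
    if (is.null(thr[[p]])) stop("missing thresholds for parameter '", p, "'", call. = FALSE)
    check_thresholds(thr[[p]], 3L)
  }
  check_thresholds(vet_cutpoints, 2L)
  for (prob in c(ordinal_noise, vet_noise, missing_rate)) {
    if (prob < 0 || prob > 1) stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (system_scale < 0 || organized_scale < 0) {
    stop("inclusion scales must be non-negative", call. = FALSE)
  }
  if (weight3_factor <= 0 || weight3_factor > 1) {
    stop("`weight3_factor` must be in (0, 1]", call. = FALSE)
  }
  structure(
    list(
      n_animals = as.integer(n_animals),
      taxon_mix = taxon_mix[hi_taxa()],
      shape_a = shape_a, shape_b = shape_b,
      ordinal_thresholds = thr, ordinal_noise = ordinal_noise,
      system_scale = system_scale, organized_scale = organized_scale,
      weight3_factor = weight3_factor,
      vet_cutpoints = vet_cutpoints, vet_noise = vet_noise,
      missing_rate = missing_rate, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

ordinal_parameters <- function() {
  c("body", "cutaneous", "parasitosis", "lymphoid_depletion", "thyroid")
}

check_thresholds <- function(x, k) {
  if (length(x) != k || any(diff(x) <= 0) || any(x <= 0) || any(x >= 1)) {
    stop("cutpoints must be ", k, " strictly increasing values in (0, 1)",
      call. = FALSE
    )
  }
  invisible(x)
}

#' Ordinal score from a latent morbidity value
#'
#' Cumulative-threshold link: the base category is the number of thresholds
#' that `m` meets or exceeds; with probability `noise` the category is
#' shifted one step up or down (equally likely, clamped to 0-3), emulating
#' observer variation. Draws from the current RNG stream; seed the stream
#' for reproducibility.
#'
#' @param m Numeric vector of latent morbidity values in [0, 1].
#' @param thresholds Three strictly increasing cutpoints in (0, 1).
#' @param noise Perturbation probability in [0, 1].
#' @return Integer vector of scores 0-3.
#' @examples
#' ordinal_from_latent(c(0, 0.4, 1), c(0.25, 0.5, 0.75), noise = 0)
#' @export
ordinal_from_latent <- function(m, thresholds, noise = 0) {
  check_thresholds(thresholds, 3L)
  if (noise < 0 || noise > 1) stop("`noise` must lie in [0, 1]", call. = FALSE)
  if (any(m < 0 | m > 1)) stop("`m` must lie in [0, 1]", call. = FALSE)
  base <- findInterval(m, thresholds)
  if (noise > 0 && length(m) > 0) {
    shift <- sample(c(-1L, 0L, 1L), length(m),
      replace = TRUE,
      prob = c(noise / 2, 1 - noise, noise / 2)
    )
    base <- pmin(3L, pmax(0L, base + shift))
  }
  as.integer(base)
}

# one representative species label per taxon, for realistic-looking tables
sim_species <- function(taxon) {
  c(
    seabird = "Spheniscus magellanicus",
    marine_mammal = "Sotalia guianensis",
    sea_turtle = "Chelonia mydas"
  )[taxon]
}

#' Simulate a necropsy cohort with known latent morbidity
#'
#' Generates complete (or, with `missing_rate > 0`, partially unassessed)
#' necropsy records from the latent-morbidity model of [sim_config()],
#' together with the ground truth: the latent morbidity per animal and a
#' simulated subjective veterinarian rating. All randomness is governed by
#' `config$seed`; identical configs yield identical cohorts.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `simulated_cohort`: a list with `records`
#'   (a record tibble scorable by [compute_hi()]), `truth` (a tibble
#'   `record_id`, `latent_morbidity`, `vet_rating`) and `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_animals = 20, seed = 42))
#' head(compute_hi(cohort$records)$hi)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_animals
    id <- sprintf("SIM-%05d", seq_len(n))
    m <- rbeta(n, config$shape_a, config$shape_b)
    taxon <- sample(hi_taxa(), n, replace = TRUE, prob = config$taxon_mix)

    draw_set <- function(scale) {
      w <- hi_systems()
      p_sys <- outer(m * scale, ifelse(w == 3L, config$weight3_factor, 1))
      p_sys <- pmin(1, p_sys)
      inc <- matrix(runif(n * length(w)), n) < p_sys
      lapply(seq_len(n), function(i) names(w)[inc[i, ]])
    }

    ord <- function(p) {
      ordinal_from_latent(m, config$ordinal_thresholds[[p]], config$ordinal_noise)
    }

    records <- tibble::tibble(
      record_id = id,
      taxon = taxon,
      species = unname(sim_species(taxon)),
      carcass_code = 2L,
      body_score = ord("body"),
      systems_macro = draw_set(config$system_scale),
      cutaneous_score = ord("cutaneous"),
      systems_organized = draw_set(config$organized_scale),
      systems_histo = draw_set(config$system_scale),
      parasitosis_score = ord("parasitosis"),
      lymphoid_depletion_score = ord("lymphoid_depletion"),
      thyroid_score = ord("thyroid")
    )

    if (config$missing_rate > 0) {
      for (p in hi_parameters()) {
        col <- param_columns()[[p]]
        drop <- runif(n) < config$missing_rate
        if (p %in% set_parameters()) {
          records[[col]][drop] <- list(NA_character_)
        } else {
          records[[col]][drop] <- NA_integer_
        }
      }
    }

    rating <- draw_vet_ratings(m, config$vet_cutpoints, config$vet_noise)

    structure(
      list(
        records = records,
        truth = tibble::tibble(
          record_id = id, latent_morbidity = m, vet_rating = rating
        ),
        config = config
      ),
      class = "simulated_cohort"
    )
  })
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(
    "<simulated_cohort>", nrow(x$records), "records; seed",
    x$config$seed, "\n"
  )
  print(table(x$truth$vet_rating))
  invisible(x)
}

draw_vet_ratings <- function(m, cutpoints, vet_noise) {
  lev <- c("good", "fair", "poor")
  idx <- findInterval(m, cutpoints) + 1L # low morbidity -> good
  if (vet_noise > 0 && length(m) > 0) {
    shift <- sample(c(-1L, 0L, 1L), length(m),
      replace = TRUE,
      prob = c(vet_noise / 2, 1 - vet_noise, vet_noise / 2)
    )
    idx <- pmin(3L, pmax(1L, idx + shift))
  }
  factor(lev[idx], levels = lev, ordered = TRUE)
}

#' Re-draw subjective veterinarian ratings for a simulated cohort
#'
#' Replaces the cohort's ratings with a fresh draw under the given
#' cutpoints and noise: rating = good/fair/poor by thresholding the latent
#' morbidity, with probability `vet_noise` of moving to an adjacent
#' category (emulating raters who systematically lean harsher or kinder).
#' Draws from the current RNG stream.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param cutpoints Two increasing cutpoints on the latent morbidity.
#' @param vet_noise Misclassification probability in [0, 1].
#' @return The cohort with `truth$vet_rating` replaced.
#' @export
simulate_vet_ratings <- function(cohort,
                                 cutpoints = cohort$config$vet_cutpoints,
                                 vet_noise = cohort$config$vet_noise) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  check_thresholds(cutpoints, 2L)
  if (vet_noise < 0 || vet_noise > 1) stop("`vet_noise` must lie in [0, 1]", call. = FALSE)
  cohort$truth$vet_rating <- draw_vet_ratings(
    cohort$truth$latent_morbidity, cutpoints, vet_noise
  )
  cohort
}
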
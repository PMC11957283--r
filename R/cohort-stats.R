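# Cohort-level statistics -----------------------------------------------------

#' Fisher-Pearson standardized moment coefficient of skewness (g1)
#'
#' `g1 = m3 / m2^(3/2)` with central moments computed with denominator `n`
#' (the population-moment form conventionally denoted g1). Negative values
#' indicate a tail toward low values — the pattern expected for a bounded
#' health index in a cohort where most animals score well.
#'
#' @param x Numeric vector, `n >= 3`, non-constant.
#' @param sample_adjusted If `TRUE`, return the sample-adjusted form
#'   `G1 = g1 * sqrt(n(n-1)) / (n-2)` instead.
#' @return A single numeric value.
#' @examples
#' skewness_g1(c(0, 0, 1)) # 1/sqrt(2)
#' @export
skewness_g1 <- function(x, sample_adjusted = FALSE) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) stop("skewness requires at least 3 values", call. = FALSE)
  if (anyNA(x)) stop("`x` must not contain NA", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop("skewness is undefined for constant data", call. = FALSE)
  m3 <- mean((x - m)^3)
  g1 <- m3 / m2^1.5
  if (sample_adjusted) g1 * sqrt(n * (n - 1)) / (n - 2) else g1
}

#' HI category bins
#'
#' HI values are classified into five categories for frequency and
#' parameter-contribution analyses: `<0.20`, `0.20-0.39`, `0.40-0.59`,
#' `0.60-0.79` and `0.80-1.0`. On the continuous HI scale these are the
#' half-open intervals [0, 0.20), [0.20, 0.40), [0.40, 0.60), [0.60, 0.80)
#' and the closed top bin [0.80, 1.0].
#'
#' @param hi Numeric vector of HI values in [0, 1]; NA passes through.
#' @return `bin_hi()`: an ordered factor over the five category labels,
#'   ordered worst to best. `hi_category_labels()`: the labels.
#' @examples
#' bin_hi(c(0.19, 0.2, 1.0))
#' @export
bin_hi <- function(hi) {
  ok <- is.na(hi) | (hi >= 0 & hi <= 1)
  if (!all(ok)) stop("HI values must lie in [0, 1]", call. = FALSE)
  idx <- findInterval(hi, c(0.20, 0.40, 0.60, 0.80)) + 1L
  factor(hi_category_labels()[idx], levels = hi_category_labels(), ordered = TRUE)
}

#' @rdname bin_hi
#' @export
hi_category_labels <- function() {
  c("<0.20", "0.20-0.39", "0.40-0.59", "0.60-0.79", "0.80-1.0")
}

#' Summarise HI values per group
#'
#' Per-group n, mean, sample standard deviation (n-1 denominator), minimum,
#' maximum and skewness [skewness_g1()]. Singleton groups report
#' `sd_hi = 0`; g1 is `NA` whenever it is undefined (n < 3 or constant
#' values).
#'
#' @param hi Numeric vector of HI values in [0, 1].
#' @param group Optional vector of group labels (species, taxon, ...) the
#'   same length as `hi`; when omitted all values form one group `"all"`.
#' @return A tibble with columns `group`, `n`, `mean_hi`, `sd_hi`, `min_hi`,
#'   `max_hi`, `g1`.
#' @examples
#' cohort_summary(c(0.2, 0.4, 0.6))
#' @export
cohort_summary <- function(hi, group = NULL) {
  if (length(hi) == 0) stop("no HI values to summarise", call. = FALSE)
  hi <- as.numeric(hi)
  if (anyNA(hi)) stop("`hi` must not contain NA; drop indeterminable results first", call. = FALSE)
  if (any(hi < 0 | hi > 1)) stop("HI values must lie in [0, 1]", call. = FALSE)
  if (is.null(group)) group <- rep("all", length(hi))
  if (length(group) != length(hi)) {
    stop("`group` must match `hi` in length", call. = FALSE)
  }
  safe_g1 <- function(x) {
    if (length(x) < 3 || length(unique(x)) == 1L) NA_real_ else skewness_g1(x)
  }
  tibble::tibble(group = as.character(group), hi = hi) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_hi = mean(.data$hi),
      sd_hi = if (dplyr::n() > 1) sd(.data$hi) else 0,
      min_hi = min(.data$hi),
      max_hi = max(.data$hi),
      g1 = safe_g1(.data$hi),
      .groups = "drop"
    )
}

# Rank-based group comparison --------------------------------------------------

check_groups <- function(values, groups) {
  if (length(values) != length(groups)) {
    stop("`values` and `groups` must have the same length", call. = FALSE)
  }
  keep <- !is.na(values) & !is.na(groups)
  values <- as.numeric(values[keep])
  g <- if (is.factor(groups)) droplevels(groups[keep]) else factor(groups[keep])
  if (nlevels(g) < 2) stop("need at least 2 non-empty groups", call. = FALSE)
  list(values = values, groups = g)
}

#' Kruskal-Wallis omnibus test on HI values across groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value on k-1 degrees
#' of freedom, as used to test whether HI differs among subjective health
#' categories. Computed via [stats::kruskal.test()]. The degenerate case of
#' all values identical returns H = 0, p = 1.
#'
#' @param values Numeric vector (e.g. HI values).
#' @param groups Group labels, same length as `values`.
#' @return A list with `H`, `df`, `p_value`, `n` and `groups` (levels).
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
kruskal_wallis <- function(values, groups) {
  d <- check_groups(values, groups)
  if (length(unique(d$values)) == 1L) {
    return(list(
      H = 0, df = nlevels(d$groups) - 1L, p_value = 1,
      n = length(d$values), groups = levels(d$groups)
    ))
  }
  kt <- stats::kruskal.test(d$values, d$groups)
  list(
    H = unname(kt$statistic), df = unname(kt$parameter),
    p_value = kt$p.value, n = length(d$values), groups = levels(d$groups)
  )
}

#' Dunn's pairwise post hoc comparisons
#'
#' Rank-based pairwise z tests following a Kruskal-Wallis test. For groups
#' a and b, `z = (Rbar_a - Rbar_b) / sqrt((N(N+1)/12 - T/(12(N-1))) *
#' (1/n_a + 1/n_b))` where `Rbar` are mean pooled mid-ranks and
#' `T = sum(t^3 - t)` over tie groups. Two-sided normal p-values, optionally
#' adjusted for the C(k,2) comparisons.
#'
#' @inheritParams kruskal_wallis
#' @param adjust Multiplicity adjustment for the pairwise p-values:
#'   `"none"` (default), `"bonferroni"` or `"holm"`.
#' @return A tibble with one row per pair: `group_a`, `group_b`, `z`,
#'   `p_raw`, `p_adjusted`.
#' @examples
#' dunn_pairwise(c(1, 2, 3, 7, 8, 9), rep(c("a", "b"), each = 3))
#' @export
dunn_pairwise <- function(values, groups, adjust = c("none", "bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  d <- check_groups(values, groups)
  g <- d$groups
  x <- d$values
  N <- length(x)
  r <- rank(x) # mid-ranks
  mean_rank <- tapply(r, g, mean)
  n_g <- tapply(r, g, length)
  tie_tab <- table(x)
  tie_term <- sum(tie_tab^3 - tie_tab)
  var_core <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))

  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  z <- p_raw <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]
    b <- pairs[2, j]
    se <- sqrt(var_core * (1 / n_g[[a]] + 1 / n_g[[b]]))
    z[j] <- if (se == 0) 0 else (mean_rank[[a]] - mean_rank[[b]]) / se
    p_raw[j] <- 2 * pnorm(-abs(z[j]))
  }
  tibble::tibble(
    group_a = pairs[1, ], group_b = pairs[2, ],
    z = z, p_raw = p_raw,
    p_adjusted = p.adjust(p_raw, method = adjust)
  )
}

#' Omnibus and pairwise comparison in one call
#'
#' Convenience wrapper running [kruskal_wallis()] and [dunn_pairwise()]
#' together, e.g. HI values against "good"/"fair"/"poor" veterinarian
#' ratings.
#'
#' @inheritParams dunn_pairwise
#' @return An object of class `hi_group_comparison`: a list with the
#'   omnibus fields of [kruskal_wallis()] plus `pairwise` and `adjust`.
#' @export
kruskal_dunn <- function(values, groups, adjust = c("none", "bonferroni", "holm")) {
  adjust <- match.arg(adjust)
  kw <- kruskal_wallis(values, groups)
  out <- c(kw, list(pairwise = dunn_pairwise(values, groups, adjust), adjust = adjust))
  class(out) <- "hi_group_comparison"
  out
}

#' @export
print.hi_group_comparison <- function(x, ...) {
  cat(sprintf(
    "Kruskal-Wallis: H = %.4g, df = %d, p = %.4g (n = %d)\n",
    x$H, x$df, x$p_value, x$n
  ))
  cat("Dunn pairwise (", x$adjust, " adjustment):\n", sep = "")
  print(as.data.frame(x$pairwise), row.names = FALSE)
  invisible(x)
}

# Parameter contribution profiles ----------------------------------------------

#' Mean parameter values per HI category
#'
#' Profiles how each of the eight parameters contributes across the five HI
#' categories: per category and parameter, the mean and standard deviation
#' of the weighted parameter values among determinable records. Body-score
#' values are standardized to [0, 1] by dividing by the taxon-specific
#' maximum (3 for seabirds and marine mammals, 6 for sea turtles) before
#' aggregation, since body score is the only parameter whose weight differs
#' between taxa.
#'
#' @param results A result tibble from [compute_hi()].
#' @param scheme The [scoring_scheme()] the results were computed under
#'   (needed for the body-score maxima).
#' @return A tibble with columns `hi_category`, `parameter`, `n`,
#'   `mean_value`, `sd_value`, `standardized` (TRUE only for the body
#'   score). Only categories that occur in the data appear.
#' @export
parameter_contribution <- function(results, scheme = scoring_scheme()) {
  res <- results[results$determinable, , drop = FALSE]
  if (nrow(res) == 0) {
    stop("no determinable HI results to profile", call. = FALSE)
  }
  body_max <- 3 * unname(scheme$body_weight[res$taxon])
  res$value_body <- res$value_body / body_max
  value_cols <- paste0("value_", hi_parameters())
  res$hi_category <- bin_hi(res$hi)
  res |>
    dplyr::select(dplyr::all_of(c("hi_category", value_cols))) |>
    tidyr::pivot_longer(
      dplyr::all_of(value_cols),
      names_to = "parameter", names_prefix = "value_", values_to = "value"
    ) |>
    dplyr::group_by(.data$hi_category, .data$parameter) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_value = mean(.data$value),
      sd_value = if (dplyr::n() > 1) sd(.data$value) else 0,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      parameter = factor(.data$parameter, levels = hi_parameters()),
      standardized = .data$parameter == "body"
    ) |>
    dplyr::arrange(.data$hi_category, .data$parameter)
}
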
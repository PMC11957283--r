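test_that("cohort_summary reproduces hand-computed statistics", {
  s <- cohort_summary(c(0.2, 0.4, 0.6))
  expect_equal(s$n, 3L)
  expect_equal(s$mean_hi, 0.4)
  expect_equal(s$sd_hi, 0.2)
  expect_equal(s$min_hi, 0.2)
  expect_equal(s$max_hi, 0.6)

  single <- cohort_summary(0.5, "only")
  expect_equal(single$sd_hi, 0)
  expect_true(is.na(single$g1))

  expect_error(cohort_summary(numeric(0)), "no HI values")
  expect_error(cohort_summary(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("cohort_summary matches direct recomputation per group", {
  withr::with_seed(7, {
    hi <- runif(200)
    grp <- sample(letters[1:4], 200, replace = TRUE)
    s <- cohort_summary(hi, grp)
    for (g in unique(grp)) {
      x <- hi[grp == g]
      row <- s[s$group == g, ]
      expect_equal(row$mean_hi, mean(x), tolerance = 1e-12)
      expect_equal(row$sd_hi, sd(x), tolerance = 1e-12)
      expect_equal(row$min_hi, min(x))
      expect_equal(row$max_hi, max(x))
      expect_equal(row$g1, skewness_g1(x), tolerance = 1e-12)
    }
  })
})

test_that("g1 skewness matches closed forms and e1071 type-1", {
  expect_equal(skewness_g1(c(1, 2, 3)), 0)
  expect_equal(skewness_g1(c(0, 0, 1)), 1 / sqrt(2), tolerance = 1e-12)
  withr::with_seed(3, {
    x <- rbeta(500, 2, 5)
    expect_equal(skewness_g1(x), e1071::skewness(x, type = 1), tolerance = 1e-12)
    # scale invariance and sign flip under negation
    expect_equal(skewness_g1(10 * x + 2), skewness_g1(x), tolerance = 1e-9)
    expect_equal(skewness_g1(-x), -skewness_g1(x), tolerance = 1e-12)
  })
  expect_equal(
    skewness_g1(x <- c(0, 0, 1, 3), sample_adjusted = TRUE),
    skewness_g1(x) * sqrt(4 * 3) / 2
  )
  expect_error(skewness_g1(c(1, 2)), "at least 3")
  expect_error(skewness_g1(c(2, 2, 2)), "constant")
})

test_that("HI categories use half-open bins with a closed top bin", {
  expect_equal(
    as.character(bin_hi(c(0, 0.19, 0.20, 0.399, 0.40, 0.599, 0.60, 0.799, 0.80, 1.0))),
    c(
      "<0.20", "<0.20", "0.20-0.39", "0.20-0.39", "0.40-0.59", "0.40-0.59",
      "0.60-0.79", "0.60-0.79", "0.80-1.0", "0.80-1.0"
    )
  )
  expect_error(bin_hi(1.01), "\\[0, 1\\]")
  # bin counts partition any cohort
  withr::with_seed(5, {
    hi <- runif(500)
    expect_equal(sum(table(bin_hi(hi))), 500)
  })
})

test_that("Kruskal-Wallis H and p match base R and the rank-sum oracle", {
  withr::with_seed(21, {
    for (rep in 1:25) {
      k <- sample(2:4, 1)
      sizes <- sample(2:4, k, replace = TRUE)
      # integer draws force ties; pooled N <= 12 keeps the oracle exact
      groups <- lapply(sizes, function(n) sample(1:5, n, replace = TRUE))
      vals <- unlist(groups)
      labs <- rep(paste0("g", seq_len(k)), sizes)
      kw <- kruskal_wallis(vals, labs)
      if (length(unique(vals)) == 1L) {
        expect_equal(kw$H, 0)
        expect_equal(kw$p_value, 1)
      } else {
        expect_equal(kw$H, oracle_kw_H(groups), tolerance = 1e-10)
        kt <- kruskal.test(vals, factor(labs))
        expect_equal(kw$p_value, kt$p.value, tolerance = 1e-12)
      }
    }
  })
})

test_that("H is invariant under strictly monotone transformation", {
  withr::with_seed(8, {
    vals <- round(runif(30), 2)
    labs <- sample(c("a", "b", "c"), 30, replace = TRUE)
    h1 <- kruskal_wallis(vals, labs)$H
    h2 <- kruskal_wallis(exp(5 * vals), labs)$H
    expect_equal(h1, h2, tolerance = 1e-12)
  })
})

test_that("Dunn z statistics match the formula oracle, with tie correction", {
  withr::with_seed(31, {
    for (rep in 1:25) {
      k <- sample(2:4, 1)
      sizes <- sample(2:4, k, replace = TRUE)
      groups <- lapply(sizes, function(n) sample(1:5, n, replace = TRUE))
      vals <- unlist(groups)
      labs <- rep(paste0("g", seq_len(k)), sizes)
      dn <- dunn_pairwise(vals, labs)
      expect_equal(nrow(dn), choose(k, 2))
      expect_equal(dn$z, unname(oracle_dunn_z(groups)), tolerance = 1e-10)
      expect_equal(dn$p_raw, 2 * pnorm(-abs(dn$z)), tolerance = 1e-12)
    }
  })
})

test_that("identical groups give H = 0 and all Dunn p-values 1", {
  vals <- rep(c(1, 2, 3), 2)
  labs <- rep(c("a", "b"), each = 3)
  same <- kruskal_wallis(rep(2, 6), labs)
  expect_equal(same$H, 0)
  expect_equal(same$p_value, 1)
  dn <- dunn_pairwise(rep(2, 6), labs)
  expect_equal(dn$z, 0)
  expect_equal(dn$p_adjusted, 1)
  # symmetric groups: z = 0 as mean ranks coincide
  expect_equal(dunn_pairwise(vals, labs)$z, 0)
})

test_that("p-value adjustment defers to stats::p.adjust", {
  withr::with_seed(13, {
    vals <- runif(40)
    labs <- sample(c("a", "b", "c", "d"), 40, replace = TRUE)
    for (m in c("bonferroni", "holm")) {
      dn <- dunn_pairwise(vals, labs, adjust = m)
      expect_equal(dn$p_adjusted, p.adjust(dn$p_raw, method = m))
    }
  })
})

test_that("parameter contributions are profiled per HI category", {
  # all-healthy cohort: every mean contribution 0 in the top category
  healthy <- dplyr::bind_rows(lapply(1:5, function(i) {
    complete_record(id = paste0("H", i), taxon = "sea_turtle")
  }))
  prof <- parameter_contribution(compute_hi(healthy))
  expect_setequal(as.character(unique(prof$hi_category)), "0.80-1.0")
  expect_true(all(prof$mean_value == 0))
  expect_true(all(prof$sd_value == 0))

  # body score standardized by the taxon maximum (6 for turtles)
  one <- complete_record(id = "B", taxon = "sea_turtle", body = 3, thyroid = 3)
  p1 <- parameter_contribution(compute_hi(one))
  expect_equal(p1$mean_value[p1$parameter == "body"], 1) # 3*2 / 6
  expect_equal(p1$mean_value[p1$parameter == "thyroid"], 6)
  expect_true(all(p1$standardized == (p1$parameter == "body")))

  # mean parameter values worsen monotonically across categories on simulation
  cohort <- simulate_cohort(sim_config(n_animals = 1500, seed = 77))
  res <- compute_hi(cohort$records)
  prof <- parameter_contribution(res)
  overall <- prof |>
    dplyr::group_by(.data$hi_category) |>
    dplyr::summarise(m = mean(.data$mean_value), .groups = "drop") |>
    dplyr::arrange(.data$hi_category)
  expect_true(all(diff(overall$m) < 0)) # worst category first, healthiest last

  expect_error(
    parameter_contribution(compute_hi(necropsy_record("x", "seabird"))),
    "no determinable"
  )
})
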
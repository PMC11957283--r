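test_that("system-count scores follow the 0 / 1-3 / 4-6 / >6 bands", {
  expect_identical(
    systemic_score_from_count(0:10),
    c(0L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 3L)
  )
  expect_error(systemic_score_from_count(-1), "between 0 and 10")
  expect_error(systemic_score_from_count(11), "between 0 and 10")
})

test_that("the highest weight among affected systems applies", {
  expect_identical(weight_for_systems(c("respiratory", "digestive", "nervous")), 3L)
  expect_identical(weight_for_systems("reproductive"), 1L)
  expect_identical(weight_for_systems(character(0)), 1L)
  expect_identical(
    weight_for_systems(list("urinary", c("musculoskeletal", "endocrine"))),
    c(2L, 3L)
  )
  expect_error(weight_for_systems("spleen"), "spleen")
})

test_that("taxon maxima are 48/51 under the default scheme and 42/45 literal", {
  expect_identical(hi_max(c("seabird", "marine_mammal", "sea_turtle")), c(48L, 48L, 51L))
  lit <- scoring_scheme("literal")
  expect_identical(hi_max(c("seabird", "marine_mammal", "sea_turtle"), lit), c(42L, 42L, 45L))
  # the turtle-seabird gap is the body-score weight difference for both variants
  for (s in list(scoring_scheme(), lit)) {
    expect_identical(hi_max("sea_turtle", s) - hi_max("seabird", s), 3L)
  }
  expect_error(hi_max("walrus"), "unknown taxon")
})

test_that("maxima are attained by the worst-case record (brute-force check)", {
  for (variant in c("paper", "literal")) {
    scheme <- scoring_scheme(variant)
    for (tx in hi_taxa()) {
      res <- compute_hi(worst_record(tx), scheme)
      expect_identical(as.integer(res$raw_sum), hi_max(tx, scheme))
      expect_equal(res$hi, 0)
    }
  }
})

test_that("the three-system worked example scores 1 x 3 = 3, HI = 1 - 3/48", {
  rec <- complete_record(
    taxon = "seabird",
    macro = c("respiratory", "digestive", "nervous")
  )
  res <- compute_hi(rec)
  expect_equal(res$value_systems_macro, 3)
  expect_equal(res$hi, 1 - 3 / 48)
})

test_that("boundary records score exactly 1 (healthy) and 0 (worst)", {
  for (tx in hi_taxa()) {
    expect_equal(compute_hi(complete_record(taxon = tx))$hi, 1)
    expect_equal(compute_hi(worst_record(tx))$hi, 0)
  }
})

test_that("any missing parameter makes the HI indeterminable, never partial", {
  base <- complete_record(taxon = "seabird", body = 1, parasitosis = 2)
  for (p in hi_parameters()) {
    rec <- base
    col <- c(
      body = "body_score", systems_macro = "systems_macro",
      cutaneous = "cutaneous_score", systems_organized = "systems_organized",
      systems_histo = "systems_histo", parasitosis = "parasitosis_score",
      lymphoid_depletion = "lymphoid_depletion_score", thyroid = "thyroid_score"
    )[[p]]
    if (p %in% c("systems_macro", "systems_organized", "systems_histo")) {
      rec[[col]] <- list(NA_character_)
    } else {
      rec[[col]] <- NA_integer_
    }
    res <- compute_hi(rec)
    expect_false(res$determinable)
    expect_true(is.na(res$hi))
    expect_identical(res$missing_parameters, p)
    f <- validate_records(rec)
    expect_identical(f$class, "missing")
    expect_identical(f$field, p)
  }
})

test_that("format violations are findings, and compute_hi refuses them", {
  rec <- complete_record(body = 5)
  expect_identical(validate_records(rec)$class, "ordinal_out_of_range")
  expect_error(compute_hi(rec), "format errors")

  rec2 <- complete_record(macro = c("digestive", "digestive"))
  expect_identical(validate_records(rec2)$class, "duplicate_system")

  rec3 <- complete_record(macro = "spleen")
  expect_identical(validate_records(rec3)$class, "unknown_system")

  rec4 <- complete_record(taxon = "walrus")
  expect_true("unknown_taxon" %in% validate_records(rec4)$class)

  expect_identical(nrow(validate_records(complete_record())), 0L)
})

test_that("compute_hi agrees with the brute-force oracle on random records", {
  withr::with_seed(101, {
    recs <- dplyr::bind_rows(lapply(1:400, function(i) random_record(paste0("G", i))))
    for (variant in c("paper", "literal")) {
      res <- compute_hi(recs, scoring_scheme(variant))
      for (i in seq_len(nrow(recs))) {
        o <- oracle_hi(
          recs$taxon[i], recs$body_score[i], recs$systems_macro[[i]],
          recs$cutaneous_score[i], recs$systems_organized[[i]],
          recs$systems_histo[[i]], recs$parasitosis_score[i],
          recs$lymphoid_depletion_score[i], recs$thyroid_score[i],
          variant
        )
        expect_equal(res$raw_sum[i], o$raw, tolerance = 1e-9)
        expect_equal(res$hi[i], o$hi, tolerance = 1e-9)
      }
      expect_true(all(res$hi >= 0 & res$hi <= 1))
      expect_true(all(res$raw_sum <= res$hi_max))
    }
  })
})

test_that("HI is monotone: worsening any parameter never raises it", {
  base <- complete_record(
    taxon = "marine_mammal", body = 1,
    macro = c("digestive", "respiratory"), cutaneous = 1,
    organized = "musculoskeletal", histo = "urinary",
    parasitosis = 1, lymphoid = 1, thyroid = 1
  )
  hi0 <- compute_hi(base)$hi
  # bump each ordinal score by one
  for (col in c(
    "body_score", "cutaneous_score", "parasitosis_score",
    "lymphoid_depletion_score", "thyroid_score"
  )) {
    rec <- base
    rec[[col]] <- rec[[col]] + 1L
    expect_lte(compute_hi(rec)$hi, hi0)
  }
  # add a system to each set
  for (col in c("systems_macro", "systems_organized", "systems_histo")) {
    for (extra in c("nervous", "reproductive")) {
      rec <- base
      rec[[col]] <- list(union(rec[[col]][[1]], extra))
      expect_lte(compute_hi(rec)$hi, hi0)
    }
  }
  # hi = 1 iff every score is zero
  expect_lt(hi0, 1)
})
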
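# Independent oracles, coded from first principles and kept deliberately
# naive; they never call the package's scoring or ranking paths.

# weight table restated from the domain definition (weight classes 1/2/3)
ORACLE_SYSTEM_W <- c(
  reproductive = 1, musculoskeletal = 1, lympho_hematopoietic = 1,
  integumentary = 1,
  digestive = 2, respiratory = 2, urinary = 2,
  nervous = 3, endocrine = 3, cardiovascular = 3
)

oracle_count_score <- function(k) {
  if (k == 0) 0 else if (k <= 3) 1 else if (k <= 6) 2 else 3
}

# brute-force HI for a single record given plain arguments
oracle_hi <- function(taxon, body, macro, cutaneous, organized, histo,
                      parasitosis, lymphoid, thyroid,
                      variant = c("paper", "literal")) {
  variant <- match.arg(variant)
  body_w <- if (taxon == "sea_turtle") 2 else 1
  set_val <- function(s, system_weighted) {
    score <- oracle_count_score(length(s))
    w <- if (!system_weighted) 1 else if (length(s) == 0) 1 else max(ORACLE_SYSTEM_W[s])
    score * w
  }
  raw <- body * body_w +
    set_val(macro, TRUE) +
    cutaneous * 1 +
    set_val(organized, variant == "paper") +
    set_val(histo, TRUE) +
    parasitosis * 1 +
    lymphoid * 2 +
    thyroid * 2
  himax <- 3 * (body_w + 3 + 1 + (if (variant == "paper") 3 else 1) + 3 + 1 + 2 + 2)
  list(raw = raw, himax = himax, hi = 1 - raw / himax)
}

# naive mid-ranks: count of strictly smaller values + half-count of ties
oracle_ranks <- function(x) {
  vapply(x, function(v) sum(x < v) + (sum(x == v) + 1) / 2, numeric(1))
}

# tie-corrected Kruskal-Wallis H from the rank-sum definition
oracle_kw_H <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- oracle_ranks(x)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (C == 0) 0 else H / C
}

# Dunn z statistics from the textbook formula, pair order (i < j)
oracle_dunn_z <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- oracle_ranks(x)
  idx <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, idx, mean)
  n <- lengths(groups)
  ties <- table(x)
  A <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  out <- c()
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (i < j) {
        se <- sqrt(A * (1 / n[i] + 1 / n[j]))
        out <- c(out, if (se == 0) 0 else (rbar[[i]] - rbar[[j]]) / se)
      }
    }
  }
  out
}

# record builders -------------------------------------------------------------

complete_record <- function(id = "R1", taxon = "seabird",
                            body = 0, macro = character(0), cutaneous = 0,
                            organized = character(0), histo = character(0),
                            parasitosis = 0, lymphoid = 0, thyroid = 0,
                            carcass_code = 2L, species = "test sp.") {
  necropsy_record(
    record_id = id, taxon = taxon, species = species,
    carcass_code = carcass_code,
    body_score = body, systems_macro = macro, cutaneous_score = cutaneous,
    systems_organized = organized, systems_histo = histo,
    parasitosis_score = parasitosis, lymphoid_depletion_score = lymphoid,
    thyroid_score = thyroid
  )
}

# the worst possible record for a taxon: every parameter at score 3 with a
# weight-3 system present in every system set
worst_record <- function(taxon, id = paste0("worst-", taxon)) {
  all_sys <- names(hi_systems())
  complete_record(
    id = id, taxon = taxon, body = 3, macro = all_sys, cutaneous = 3,
    organized = all_sys, histo = all_sys, parasitosis = 3,
    lymphoid = 3, thyroid = 3
  )
}

# a seeded random complete record (used by grid/property tests)
random_record <- function(id, taxon = sample(hi_taxa(), 1), max_set = 10) {
  sys <- names(hi_systems())
  rset <- function() sample(sys, sample(0:max_set, 1))
  complete_record(
    id = id, taxon = taxon,
    body = sample(0:3, 1), macro = rset(), cutaneous = sample(0:3, 1),
    organized = rset(), histo = rset(), parasitosis = sample(0:3, 1),
    lymphoid = sample(0:3, 1), thyroid = sample(0:3, 1)
  )
}
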
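# three-record planted chain: C-B records, B-A record, no C-A record
chain_corpus <- function(with_ca_record = FALSE) {
  recs <- list(
    medline_record("1", "A study.",
      "Conceptb increases severity in patients with conceptc.",
      c("conceptc", "conceptb"), 1980),
    medline_record("2", "Another study.",
      "Conceptb increases concepta levels in serum.",
      c("conceptb", "concepta"), 1981),
    medline_record("3", "Background.", "Nothing here.",
      c("conceptx"), 1982)
  )
  if (with_ca_record) {
    recs[[4]] <- medline_record("4", "Joint.", "",
                                c("conceptc", "concepta"), 1983)
  }
  recs
}

test_that("discover_targets keeps the planted chain and applies exclusions", {
  recs <- chain_corpus()
  mesh <- build_index(recs, "mesh_field")
  got <- discover_targets("conceptb", mesh, preliminary_b = "conceptb",
                          start = "conceptc")
  expect_identical(names(got), "concepta")
  expect_identical(got[["concepta"]], "conceptb")

  # a target also co-occurring with C is excluded
  recs2 <- chain_corpus(with_ca_record = TRUE)
  mesh2 <- build_index(recs2, "mesh_field")
  got2 <- discover_targets("conceptb", mesh2, "conceptb", "conceptc")
  expect_false("concepta" %in% names(got2))

  expect_warning(none <- discover_targets(character(), mesh, "conceptb", "conceptc"),
                 "no positive linking concepts")
  expect_length(none, 0L)
})

test_that("discovered target set equals the brute-force three-loop scan", {
  sim <- generate_corpus(corpus_spec(seed = 27, n_records = 40, relevant_b = 2,
                                     decoy_b = 6, n_too_general = 1,
                                     b_background = 1))
  recs <- sim$records
  truth <- sim$truth
  mesh <- build_index(recs, "mesh_field")
  prelim <- candidate_linking_concepts(mesh, truth$start)
  tmap <- generate_semantic_types(truth$spec)
  for (positive in list(truth$relevant_b, prelim)) {
    for (tf in list(NULL, type_filter_config(enabled = TRUE))) {
      got <- discover_targets(positive, mesh, prelim, truth$start, tmap, tf)
      want <- oracle_targets(positive, recs, prelim, truth$start,
                             type_map = if (!is.null(tf)) tmap,
                             target_types = if (!is.null(tf)) tf$target_types)
      expect_identical(names(got), want)
      # per-target linking sets: positive B's co-occurring with the target
      for (a in names(got)) {
        expect_setequal(got[[a]],
          positive[vapply(positive, function(b) cooc_count(mesh, a, b) >= 1,
                          logical(1))])
      }
    }
  }
})

test_that("useful_linking_set distinguishes rule1 from rule2 evidence", {
  recs <- list(
    medline_record("1", "T.",
      paste("Conceptb was measured in plasma.",
            "Several controls were used.",
            "Concepta readings were also recorded."),
      c("conceptb", "concepta"), 1980),
    medline_record("2", "T two.",
      "Conceptd increases concepta levels in serum.",
      c("conceptd", "concepta"), 1981)
  )
  lex <- interaction_lexicon(c("increase", "increases"))
  scan <- scan_corpus(recs, c("concepta", "conceptb", "conceptd"))
  linking <- c("conceptb", "conceptd")
  expect_setequal(useful_linking_set("concepta", linking, "plain_ltc", scan, lex),
                  linking)
  # B shares only an abstract with A -> rule1 yes, rule2 no
  expect_setequal(useful_linking_set("concepta", linking, "rule1", scan, lex),
                  c("conceptb", "conceptd"))
  expect_identical(useful_linking_set("concepta", linking, "rule2", scan, lex),
                   "conceptd")
  expect_identical(useful_linking_set("concepta", character(), "rule2", scan, lex),
                   character())
  expect_error(useful_linking_set("concepta", linking, "rule2", scan,
                                  interaction_lexicon(character())),
               "interaction lexicon")
})

test_that("rule sets equal the exhaustive sentence-scan oracle", {
  sim <- generate_corpus(corpus_spec(seed = 29, n_records = 45, relevant_b = 3,
                                     decoy_b = 6, n_too_general = 1,
                                     interaction_rate = 0.5, b_background = 1))
  recs <- sim$records
  truth <- sim$truth
  lex <- default_interaction_lexicon()
  concepts <- unique(c(truth$start, truth$relevant_b, truth$decoy_b,
                       truth$targets))
  scan <- scan_corpus(recs, concepts)
  linking <- c(truth$relevant_b, truth$decoy_b)
  for (a in truth$targets) {
    for (rule in c("rule1", "rule2")) {
      got <- useful_linking_set(a, linking, rule, scan, lex)
      want <- oracle_useful(a, linking, rule, recs, lex$words)
      expect_setequal(got, want)
    }
  }
})

test_that("rank_targets implements tie-aware dense ranking", {
  df <- data.frame(concept = c("carbon", "magnesium", "ions", "nitrogen"),
                   useful_ltc = c(39L, 39L, 37L, 34L))
  ranked <- rank_targets(df)
  expect_identical(ranked$rank, c(1L, 1L, 2L, 3L))
  # within-rank order alphabetical
  expect_identical(ranked$concept[1:2], c("carbon", "magnesium"))
  expect_identical(rank_targets(df[3, ])$rank, 1L)
})

test_that("dense ranks equal the strictly-larger-counts oracle", {
  set.seed(37)
  for (k in 1:25) {
    counts <- sample(0:12, sample(1:15, 1), replace = TRUE)
    df <- data.frame(concept = sprintf("t%02d", seq_along(counts)),
                     useful_ltc = counts)
    ranked <- rank_targets(df)
    want <- oracle_dense_rank(ranked$useful_ltc)
    expect_identical(ranked$rank, as.integer(want))
    # contiguous 1..k over distinct counts
    expect_identical(sort(unique(ranked$rank)),
                     seq_len(length(unique(counts))))
  }
})

test_that("rank_in_types re-ranks within a semantic-type group", {
  tmap <- load_semantic_types(c("carbon\tElement", "magnesium\tElement",
                                "ions\tIon", "oil\tLipid"))
  df <- data.frame(concept = c("carbon", "magnesium", "ions", "oil"),
                   useful_ltc = c(39L, 39L, 37L, 32L))
  ranked <- rank_targets(df)
  grp <- rank_in_types(ranked, tmap, c("Element", "Ion", "Isotope"))
  expect_identical(grp$concept, c("carbon", "magnesium", "ions"))
  expect_identical(grp$type_rank, c(1L, 1L, 2L))
})

test_that("percent_useful_ltc implements the ratio with its guards", {
  expect_equal(round(percent_useful_ltc(148, 1852), 1), 8.0)
  expect_identical(percent_useful_ltc(0, 5), 0)
  expect_identical(percent_useful_ltc(7, 7), 100)
  expect_error(percent_useful_ltc(1, 0), "n_all")
  expect_error(percent_useful_ltc(5, 3), "n_useful")
})

test_that("run_open_discovery: classifier filtering yields a subset of 'all'", {
  sim <- generate_corpus(corpus_spec(seed = 33))
  recs <- sim$records
  lex <- default_interaction_lexicon()
  tmap <- generate_semantic_types(sim$truth$spec)
  res_all <- run_open_discovery(
    discovery_config(sim$truth$start, use_classifier = FALSE,
                     type_filter = type_filter_config(enabled = FALSE)),
    recs, lex, tmap)
  res_pos <- run_open_discovery(
    discovery_config(sim$truth$start, use_classifier = TRUE,
                     type_filter = type_filter_config(enabled = TRUE)),
    recs, lex, tmap)
  pos_b <- res_pos$linking$concept[res_pos$linking$label == "positive"]
  all_b <- res_all$linking$concept
  expect_true(all(pos_b %in% all_b))
  expect_lt(length(pos_b), length(all_b))
})

test_that("degenerate configuration reduces to pure co-occurrence LBD", {
  recs <- chain_corpus()
  lex <- default_interaction_lexicon()
  cfg <- discovery_config("conceptc", rule = "plain_ltc",
                          use_classifier = FALSE,
                          type_filter = type_filter_config(enabled = FALSE))
  res <- run_open_discovery(cfg, recs, lex)
  expect_identical(res$targets$concept, "concepta")
  expect_identical(res$targets$ltc, res$targets$useful_ltc)
  expect_identical(res$evaluation$percentage, 100)
})

test_that("stage errors carry the stage name", {
  recs <- chain_corpus()
  cfg <- discovery_config("conceptc", rule = "rule2", use_classifier = FALSE)
  expect_error(run_open_discovery(cfg, recs, interaction_lexicon(character())),
               "stage 'useful_linking_set'")
  cfg2 <- discovery_config("conceptc", max_year = 1900, use_classifier = FALSE)
  expect_error(run_open_discovery(cfg2, recs, default_interaction_lexicon()),
               "filter_by_year")
})
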
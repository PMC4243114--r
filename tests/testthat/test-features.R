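test_that("mim reproduces hand-evaluated scores and conventions", {
  # (2/8) / ((2/8)*(2/8)) = 4 -> 2 bits
  expect_equal(mim(2, 2, 2, 8), 2.0)
  # independence: joint equals product of marginals -> exactly 0
  expect_identical(mim(1, 2, 2, 4), 0)
  expect_identical(mim(4, 4, 8, 8), 0)
  # undefined cases hit the floor
  expect_identical(mim(0, 5, 3, 10), -20)
  expect_identical(mim(0, 0, 0, 10, floor = -7), -7)
  # count ordering violations error
  expect_error(mim(3, 2, 5, 10), "invalid counts")
  expect_error(mim(1, 2, 11, 10), "invalid counts")
  expect_error(mim(1, 1, 1, 0), "n_docs")
})

test_that("mim agrees with direct formula evaluation, is symmetric, monotone", {
  set.seed(19)
  for (k in 1:1000) {
    n_docs <- sample(1:500, 1)
    n_a <- sample(1:n_docs, 1)
    n_b <- sample(1:n_docs, 1)
    n_ab <- sample(0:min(n_a, n_b), 1)
    got <- mim(n_ab, n_a, n_b, n_docs)
    want <- if (n_ab == 0) -20 else {
      log2((n_ab / n_docs) / ((n_a / n_docs) * (n_b / n_docs)))
    }
    expect_equal(got, want, tolerance = 1e-12)
    expect_identical(got, mim(n_ab, n_b, n_a, n_docs))
  }
  # strictly increasing in n_ab for n_ab >= 1, other counts fixed
  vals <- vapply(1:6, function(j) mim(j, 8, 9, 50), numeric(1))
  expect_true(all(diff(vals) > 0))
})

# shared fixture: a planted two-record corpus exercising each feature
feature_fixture <- function() {
  recs <- list(
    medline_record("1", "A study of factors.",
      paste("Conceptc was diagnosed in all patients.",
            "Conceptb increases symptom severity in conceptc."),
      c("conceptc", "conceptb"), 1980),
    medline_record("2", "Another study.",
      paste("Conceptc was present.",
            "No relevant terms here.",
            "Conceptd was separately measured."),
      c("conceptc", "conceptd"), 1981),
    medline_record("3", "Mesh only record.",
      "Nothing textual about the pair.",
      c("conceptc", "concepte"), 1982)
  )
  concepts <- c("conceptc", "conceptb", "conceptd", "concepte")
  scan <- scan_corpus(recs, concepts)
  indices <- lapply(c(mesh_field = "mesh_field", tiab = "tiab",
                      sentence = "sentence", window = "window"),
                    function(sc) build_index(recs, sc, concepts = concepts,
                                             scan = scan))
  list(recs = recs, scan = scan, indices = indices,
       lex = interaction_lexicon(c("increase", "increases")))
}

test_that("extract_features on planted sentence/window/abstract evidence", {
  fx <- feature_fixture()
  # same sentence with an interaction word: f3..f6 all 1
  v <- extract_features("conceptc", "conceptb", fx$indices, fx$scan, fx$lex)
  expect_identical(unlist(v[c("f3", "f4", "f5", "f6", "f7")]),
                   c(f3 = 1L, f4 = 1L, f5 = 1L, f6 = 1L, f7 = 1L))
  expect_equal(v$f1, log2((1 / 3) / ((3 / 3) * (1 / 3))))  # 0: C in all docs
  # abstract-distance co-occurrence only: f7 without f3/f5
  v2 <- extract_features("conceptc", "conceptd", fx$indices, fx$scan, fx$lex)
  expect_identical(unlist(v2[c("f3", "f4", "f5", "f6", "f7")]),
                   c(f3 = 0L, f4 = 0L, f5 = 0L, f6 = 0L, f7 = 1L))
  # strict reading of feature VII excludes window-level co-occurrence
  v2s <- extract_features("conceptc", "conceptd", fx$indices, fx$scan, fx$lex,
                          strict_f7 = TRUE)
  expect_identical(v2s$f7, 1L)
  vs <- extract_features("conceptc", "conceptb", fx$indices, fx$scan, fx$lex,
                         strict_f7 = TRUE)
  expect_identical(vs$f7, 0L)
  # MeSH-only co-occurrence: textual features all 0, f1 above floor
  v3 <- extract_features("conceptc", "concepte", fx$indices, fx$scan, fx$lex)
  expect_identical(sum(unlist(v3[c("f3", "f4", "f5", "f6", "f7")])), 0L)
  expect_gt(v3$f1, -20)
  expect_identical(v3$f2, -20)
})

test_that("feature vectors equal the exhaustive sentence-scan oracle", {
  sim <- generate_corpus(corpus_spec(seed = 17, n_records = 50, relevant_b = 3,
                                     decoy_b = 8, n_too_general = 1,
                                     abbrev_rate = 0.5, interaction_rate = 0.6,
                                     b_background = 1))
  recs <- sim$records
  lex <- default_interaction_lexicon()
  start <- sim$truth$start
  concepts <- unique(c(start, sim$truth$relevant_b, sim$truth$decoy_b,
                       sim$truth$targets))
  scan <- scan_corpus(recs, concepts)
  indices <- lapply(c(mesh_field = "mesh_field", tiab = "tiab",
                      sentence = "sentence", window = "window"),
                    function(sc) build_index(recs, sc, concepts = concepts,
                                             scan = scan))
  feats <- feature_matrix(start, setdiff(concepts, start), indices, scan, lex)
  for (k in seq_len(nrow(feats))) {
    want <- oracle_features(start, feats$concept[k], recs, lex$words)
    got <- unlist(feats[k, c("f3", "f4", "f5", "f6", "f7")])
    expect_identical(got, want, label = feats$concept[k])
  }
  # determinism: identical corpora and configs give identical vectors
  feats2 <- feature_matrix(start, setdiff(concepts, start), indices, scan, lex)
  expect_identical(feats, feats2)
})

test_that("per-vector implication chain f4 => f3 => f5 and f6 <= f5 holds", {
  sim <- generate_corpus(corpus_spec(seed = 23, interaction_rate = 0.5,
                                     abbrev_rate = 0.5))
  recs <- sim$records
  start <- sim$truth$start
  lex <- default_interaction_lexicon()
  mesh <- build_index(recs, "mesh_field")
  cands <- candidate_linking_concepts(mesh, start)
  concepts <- unique(c(start, names(mesh$occ)))
  scan <- scan_corpus(recs, concepts)
  indices <- list(mesh_field = mesh,
                  tiab = build_index(recs, "tiab", scan = scan),
                  sentence = build_index(recs, "sentence", scan = scan),
                  window = build_index(recs, "window", scan = scan))
  feats <- feature_matrix(start, cands, indices, scan, lex)
  expect_gt(nrow(feats), 10)
  expect_true(all(feats$f4 <= feats$f3))
  expect_true(all(feats$f3 <= feats$f5))
  expect_true(all(feats$f6 <= feats$f5))
  expect_true(all(feats$f4 <= feats$f6))
  expect_true(all(unlist(feats[c("f3", "f4", "f5", "f6", "f7")]) %in% 0:1))
  expect_true(all(is.finite(feats$f1)), all(is.finite(feats$f2)))
})

test_that("feature matrix TSV round-trips with an optional label column", {
  fx <- feature_fixture()
  feats <- feature_matrix("conceptc", c("conceptb", "conceptd"),
                          fx$indices, fx$scan, fx$lex)
  feats$label <- c("positive", "negative")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(feats, path)
  back <- read_feature_matrix(path)
  expect_identical(back$concept, feats$concept)
  expect_identical(back$label, feats$label)
  expect_equal(back$f1, feats$f1)
})
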
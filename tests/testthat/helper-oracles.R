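# Independent brute-force oracles. These deliberately avoid the package's
# own counting/segmentation code paths: character loops, per-record double
# loops over concept pairs, and direct sentence scans.

# character-level sentence splitter implementing the stated boundary rule:
# terminal punctuation run, then whitespace, optional quote, then an
# uppercase letter or digit; no boundary after listed abbreviations or
# single-letter tokens
oracle_split_sentences <- function(text,
                                   exceptions = c("vs", "al", "fig", "figs",
                                                  "no", "dr", "st", "cf",
                                                  "ca", "approx", "spp")) {
  chars <- strsplit(text, "")[[1]]
  n <- length(chars)
  sents <- character()
  start <- 1L
  i <- 1L
  is_ws <- function(ch) grepl("^[[:space:]]$", ch)
  while (i <= n) {
    if (chars[i] %in% c(".", "!", "?")) {
      j <- i
      while (j < n && chars[j + 1L] %in% c(".", "!", "?")) j <- j + 1L
      k <- j + 1L
      if (k <= n && is_ws(chars[k])) {
        while (k <= n && is_ws(chars[k])) k <- k + 1L
        kk <- k
        if (kk <= n && chars[kk] %in% c("\"", "'")) kk <- kk + 1L
        if (kk <= n && grepl("^[A-Z0-9]$", chars[kk])) {
          m <- i - 1L
          tok <- ""
          while (m >= 1L && grepl("^[A-Za-z]$", chars[m])) {
            tok <- paste0(chars[m], tok)
            m <- m - 1L
          }
          boundary <- if (nchar(tok) == 1L) {
            # single uppercase letter (initial) or dotted abbreviation
            # letter ("e.g.") suppresses the boundary
            !(grepl("^[A-Z]$", tok) || (m >= 1L && chars[m] == "."))
          } else {
            !(tolower(tok) %in% exceptions)
          }
          if (boundary) {
            sents <- c(sents, substr(text, start, j))
            start <- k
            i <- j + 1L
            next
          }
        }
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (start <= n) sents <- c(sents, substr(text, start, n))
  trimws(sents)
}

# tokenizer-free scan: does any whole token of `text` equal a lexicon word?
oracle_has_interaction <- function(words, text) {
  if (length(words) == 0L) return(FALSE)
  toks <- regmatches(text, gregexpr("[A-Za-z0-9-]+", text))[[1]]
  any(tolower(toks) %in% tolower(words))
}

# per-record sentence index sets for each concept, via the package's
# find_mentions (the oracle below only re-derives the *counting*, which is
# what the index oracle checks)
oracle_mention_map <- function(records, concepts) {
  lapply(records, function(r) {
    men <- find_mentions(r, concepts)
    split(men$sentence_index, men$concept)
  })
}

# exhaustive per-record double loop over concept pairs at a scope
oracle_index <- function(records, scope, concepts) {
  concepts <- sort(unique(normalize_concept(concepts)))
  mention_map <- if (scope != "mesh_field") oracle_mention_map(records, concepts)
  occ <- stats::setNames(rep(0L, length(concepts)), concepts)
  pair_names <- character()
  cooc <- integer()
  for (ri in seq_along(records)) {
    r <- records[[ri]]
    present <- if (scope == "mesh_field") {
      intersect(concepts, r$mesh_terms)
    } else {
      names(mention_map[[ri]])
    }
    for (con in present) occ[con] <- occ[con] + 1L
    if (length(present) < 2L) next
    for (x in present) {
      for (y in present) {
        if (x >= y) next
        joint <- if (scope %in% c("mesh_field", "tiab")) {
          TRUE
        } else {
          dx <- mention_map[[ri]][[x]]
          dy <- mention_map[[ri]][[y]]
          d <- min(abs(outer(dx, dy, "-")))
          if (scope == "sentence") d == 0L else d <= 1L
        }
        if (joint) {
          key <- paste(x, y, sep = "\r")
          pos <- match(key, pair_names)
          if (is.na(pos)) {
            pair_names <- c(pair_names, key)
            cooc <- c(cooc, 1L)
          } else {
            cooc[pos] <- cooc[pos] + 1L
          }
        }
      }
    }
  }
  list(occ = occ[occ > 0L], cooc = stats::setNames(cooc, pair_names))
}

# compare a cooc_index against the oracle's counts
expect_index_matches_oracle <- function(index, records, scope, concepts) {
  oracle <- oracle_index(records, scope, concepts)
  got_occ <- index$occ[sort(names(index$occ))]
  want_occ <- oracle$occ[sort(names(oracle$occ))]
  expect_identical(names(got_occ), names(want_occ))
  expect_identical(unname(as.integer(got_occ)), unname(as.integer(want_occ)))
  got_pairs <- stats::setNames(as.integer(index$cooc$n),
                               paste(index$cooc$a, index$cooc$b, sep = "\r"))
  got_pairs <- got_pairs[sort(names(got_pairs))]
  want_pairs <- oracle$cooc[sort(names(oracle$cooc))]
  expect_identical(names(got_pairs), names(want_pairs))
  expect_identical(unname(got_pairs), unname(as.integer(want_pairs)))
}

# direct sentence-scan feature oracle for one (start, concept) pair
oracle_features <- function(start, concept, records, lexicon_words) {
  f <- c(f3 = 0L, f4 = 0L, f5 = 0L, f6 = 0L, f7 = 0L)
  for (r in records) {
    sents <- segment_sentences(r)
    men <- find_mentions(r, c(start, concept), sents)
    sa <- men$sentence_index[men$concept == start]
    sb <- men$sentence_index[men$concept == concept]
    if (length(sa) == 0L || length(sb) == 0L) next
    iw <- vapply(sents$text, function(tx) oracle_has_interaction(lexicon_words, tx),
                 logical(1))
    for (i in sa) {
      for (j in sb) {
        if (i == j) {
          f["f3"] <- 1L
          if (iw[[i + 1L]]) f["f4"] <- 1L
        }
        if (abs(i - j) <= 1L) {
          f["f5"] <- 1L
          if (any(iw[unique(c(i, j)) + 1L])) f["f6"] <- 1L
        }
      }
    }
    ab <- sents$index[sents$source == "abstract"]
    if (any(sa %in% ab) && any(sb %in% ab)) f["f7"] <- 1L
  }
  f
}

# rule sets by direct scan
oracle_useful <- function(target, linking, rule, records, lexicon_words) {
  keep <- character()
  for (b in linking) {
    hit <- FALSE
    for (r in records) {
      sents <- segment_sentences(r)
      men <- find_mentions(r, c(target, b), sents)
      st <- men$sentence_index[men$concept == target]
      sb <- men$sentence_index[men$concept == b]
      if (length(st) == 0L || length(sb) == 0L) next
      if (rule == "rule1") { hit <- TRUE; break }
      shared <- intersect(st, sb)
      for (s in shared) {
        if (oracle_has_interaction(lexicon_words, sents$text[sents$index == s])) {
          hit <- TRUE
          break
        }
      }
      if (hit) break
    }
    if (hit) keep <- c(keep, b)
  }
  keep
}

# three-loop target discovery scan
oracle_targets <- function(positive_b, records, preliminary_b, start,
                           type_map = NULL, target_types = NULL) {
  mesh <- lapply(records, function(r) r$mesh_terms)
  cooccurs <- function(x, y) {
    any(vapply(mesh, function(m) x %in% m && y %in% m, logical(1)))
  }
  cands <- character()
  for (b in positive_b) {
    for (m in mesh) {
      if (b %in% m) cands <- union(cands, setdiff(m, b))
    }
  }
  out <- character()
  for (a in cands) {
    if (a == start) next
    if (a %in% preliminary_b) next
    if (cooccurs(a, start)) next
    if (!any(vapply(positive_b, function(b) cooccurs(a, b), logical(1)))) next
    if (!is.null(type_map) &&
        !has_type(type_map, a, target_types)) next
    out <- c(out, a)
  }
  sort(out)
}

# dense rank = 1 + number of strictly larger distinct counts
oracle_dense_rank <- function(counts) {
  vapply(counts, function(ct) 1L + length(unique(counts[counts > ct])),
         integer(1))
}

# small shared fixture: a tiny hand-written corpus for unit tests
tiny_corpus <- function() {
  list(
    medline_record("10",
      title = "Raynaud syndrome and blood viscosity.",
      abstract = paste("Patients with Raynaud syndrome were studied.",
                       "Blood viscosity increases platelet aggregation in cold."),
      mesh_terms = c("Raynaud Syndrome", "Blood Viscosity"),
      year = 1980),
    medline_record("11",
      title = "Fish oil in dietary studies.",
      abstract = paste("Fish oil reduces blood viscosity in volunteers.",
                       "Dietary fats were recorded."),
      mesh_terms = c("Fish Oil", "Blood Viscosity", "Dietary Fats"),
      year = 1982),
    medline_record("12",
      title = "A cohort without relevant terms.",
      abstract = "Nothing notable was found. Controls were healthy.",
      mesh_terms = c("Humans"),
      year = 1984)
  )
}
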
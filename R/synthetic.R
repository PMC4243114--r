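#' Specification for a synthetic MEDLINE-like corpus
#'
#' Describes a corpus with planted C-B-A co-occurrence chains: C-literature
#' records (the starting concept with relevant and decoy linking concepts),
#' A-literature records (relevant linking concepts with target concepts,
#' never the starting concept), and background noise records. Planted
#' targets never co-occur with the starting concept in any field, the ABC
#' model's defining constraint.
#'
#' Defaults mirror the planted-chain recovery setting used throughout the
#' test suite: 3 relevant linking concepts, 20 decoys, 1 target,
#' interaction sentences always planted.
#'
#' @param n_records total corpus size (planted records plus noise fill).
#' @param start_concept the starting concept C.
#' @param relevant_b names (or a count) of planted relevant linking concepts.
#' @param decoy_b names (or a count) of planted irrelevant linking concepts;
#'   decoys cycle through three kinds: `mesh_only`, `separated` (title/
#'   abstract co-occurrence in non-adjacent sentences only),
#'   `no_interaction` (same-sentence co-occurrence without an interaction
#'   word), plus `too_general` decoys with inflated document frequency.
#' @param targets names (or a count) of planted target concepts, reachable
#'   only through the relevant linking concepts.
#' @param interaction_rate probability a planted C-B or B-A sentence carries
#'   an interaction word (otherwise a neutral verb is used).
#' @param abbrev_rate probability a relevant linking concept is introduced
#'   as `"Full Name (ABBR)"` with an abbreviation-only follow-up sentence.
#' @param noise_mesh_rate probability of one extra random noise MeSH term
#'   per record.
#' @param n_too_general number of additional high-document-frequency decoys.
#' @param c_per_relevant,c_per_decoy,a_per_link records planted per
#'   relevant/decoy linking concept and per (target, relevant) link.
#' @param b_background background records per decoy linking concept (its own
#'   literature, without the starting concept), so decoys carry realistic
#'   marginal document frequencies.
#' @param seed integer RNG seed; identical specs generate byte-identical
#'   corpora.
#' @return a validated `corpus_spec` list.
#' @export
corpus_spec <- function(n_records = 120L,
                        start_concept = "startdisease",
                        relevant_b = 3L,
                        decoy_b = 20L,
                        targets = 1L,
                        interaction_rate = 1.0,
                        abbrev_rate = 0.2,
                        noise_mesh_rate = 0.3,
                        n_too_general = 2L,
                        c_per_relevant = 3L,
                        c_per_decoy = 2L,
                        a_per_link = 2L,
                        b_background = 2L,
                        seed = 1L) {
  name_seq <- function(x, prefix) {
    if (is.numeric(x)) sprintf("%s%02d", prefix, seq_len(x)) else normalize_concept(x)
  }
  spec <- list(
    n_records = as.integer(n_records),
    start_concept = normalize_concept(start_concept),
    relevant_b = name_seq(relevant_b, "linkrel"),
    decoy_b = name_seq(decoy_b, "linkdec"),
    too_general_b = sprintf("generalterm%02d", seq_len(n_too_general)),
    targets = name_seq(targets, "targcon"),
    interaction_rate = interaction_rate,
    abbrev_rate = abbrev_rate,
    noise_mesh_rate = noise_mesh_rate,
    c_per_relevant = as.integer(c_per_relevant),
    c_per_decoy = as.integer(c_per_decoy),
    a_per_link = as.integer(a_per_link),
    b_background = as.integer(b_background),
    seed = as.integer(seed)
  )
  rates <- c(spec$interaction_rate, spec$abbrev_rate, spec$noise_mesh_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  if (length(intersect(spec$relevant_b, spec$decoy_b)) > 0L) {
    stop("relevant_b and decoy_b must be disjoint", call. = FALSE)
  }
  overlap <- intersect(spec$targets,
                       c(spec$start_concept, spec$relevant_b, spec$decoy_b))
  if (length(overlap) > 0L) {
    stop("targets must be distinct from C and the linking concepts: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  }
  n_planted <- length(spec$relevant_b) * spec$c_per_relevant +
    (length(spec$decoy_b) + length(spec$too_general_b)) * spec$c_per_decoy +
    length(spec$decoy_b) * spec$b_background +
    length(spec$targets) * length(spec$relevant_b) * spec$a_per_link
  if (spec$n_records < n_planted) {
    stop("n_records (", spec$n_records, ") smaller than planted records (",
         n_planted, ")", call. = FALSE)
  }
  structure(spec, class = "corpus_spec")
}

.cap <- function(x) {
  paste0(toupper(substr(x, 1L, 1L)), substr(x, 2L, nchar(x)))
}

.generator_verbs <- function() {
  c("increases", "reduces", "aggravates", "inhibits", "promotes")
}

#' Generate a synthetic corpus with ground truth
#'
#' Produces MEDLINE records per the [corpus_spec()] and a ground-truth log
#' of everything planted: per-record MeSH lists, per-sentence concept sets,
#' interaction-word flags, concept roles, and the expected relevance labels.
#' Sentences are template-generated; the features only depend on mention and
#' lexicon geometry, not on fluency.
#'
#' @param spec a [corpus_spec()].
#' @return list with `records` (a `medline_corpus`) and `truth` (see
#'   [planted_counts()]); `truth$labels` maps each planted linking concept
#'   to `relevant`/`decoy` and its decoy kind.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  rng <- .seeded_rng(spec$seed)
  verbs <- .generator_verbs()
  cpt <- spec$start_concept
  n_noise_vocab <- 15L
  noise_vocab <- sprintf("noisec%02d", seq_len(n_noise_vocab))

  records <- list()
  log <- list()
  pmid_n <- 0L
  add_record <- function(mesh, sentences, year) {
    # sentences: list of list(text=, concepts=, iw=); first is the title
    pmid_n <<- pmid_n + 1L
    pmid <- sprintf("%06d", pmid_n)
    title <- sentences[[1]]$text
    abstract <- paste(vapply(sentences[-1], function(s) s$text, character(1)),
                      collapse = " ")
    records[[length(records) + 1L]] <<-
      medline_record(pmid, title, abstract, mesh, year)
    log[[length(log) + 1L]] <<- list(
      pmid = pmid, mesh = unique(normalize_concept(mesh)), year = year,
      sentences = lapply(sentences, function(s)
        list(concepts = s$concepts, iw = isTRUE(s$iw),
             source = NULL))
    )
  }
  title_sentence <- function() {
    list(text = "A study of clinical parameters in a patient cohort.",
         concepts = character(), iw = FALSE)
  }
  pick_year <- function() 1975L + as.integer(floor(rng$runif(1) * 11))
  maybe_noise_mesh <- function(mesh) {
    if (rng$runif(1) < spec$noise_mesh_rate) {
      mesh <- c(mesh, rng$sample(noise_vocab, 1L))
    }
    mesh
  }

  abbrev_token <- function(b) toupper(gsub("[^a-z0-9]", "", substr(b, 5L, 9L)))

  # --- C literature: relevant linking concepts -------------------------------
  for (b in spec$relevant_b) {
    for (k in seq_len(spec$c_per_relevant)) {
      use_iw <- rng$runif(1) < spec$interaction_rate
      use_ab <- rng$runif(1) < spec$abbrev_rate
      verb <- if (use_iw) rng$sample(verbs, 1L) else "accompanies"
      bt <- if (use_ab) paste0(.cap(b), " (", abbrev_token(b), ")") else .cap(b)
      sents <- list(
        title_sentence(),
        list(text = paste0("Patients with ", cpt, " were examined over two years."),
             concepts = cpt, iw = FALSE),
        list(text = paste0(bt, " ", verb, " vascular tone in patients with ",
                           cpt, "."),
             concepts = c(b, cpt), iw = use_iw)
      )
      if (use_ab) {
        sents[[length(sents) + 1L]] <-
          list(text = paste0(abbrev_token(b), " levels were notable in the cohort."),
               concepts = b, iw = FALSE)
      }
      add_record(maybe_noise_mesh(c(cpt, b)), sents, pick_year())
    }
  }

  # --- C literature: decoys --------------------------------------------------
  decoy_kind <- function(i) c("mesh_only", "separated", "no_interaction")[(i - 1L) %% 3L + 1L]
  for (i in seq_along(spec$decoy_b)) {
    b <- spec$decoy_b[i]
    kind <- decoy_kind(i)
    for (k in seq_len(spec$c_per_decoy)) {
      sents <- switch(kind,
        mesh_only = list(
          title_sentence(),
          list(text = paste0("Patients with ", cpt, " were examined."),
               concepts = cpt, iw = FALSE)
        ),
        separated = list(
          title_sentence(),
          list(text = paste0("Patients with ", cpt, " were examined."),
               concepts = cpt, iw = FALSE),
          list(text = "The cohort was followed for several months.",
               concepts = character(), iw = FALSE),
          list(text = paste0(.cap(b), " was recorded in registry data."),
               concepts = b, iw = FALSE)
        ),
        no_interaction = list(
          title_sentence(),
          list(text = paste0(.cap(b), " accompanies clinical findings in patients with ",
                             cpt, "."),
               concepts = c(b, cpt), iw = FALSE)
        )
      )
      add_record(maybe_noise_mesh(c(cpt, b)), sents, pick_year())
    }
  }
  # decoy background literature (no C): realistic marginal DF for decoys
  for (b in spec$decoy_b) {
    for (k in seq_len(spec$b_background)) {
      sents <- list(
        title_sentence(),
        list(text = paste0(.cap(b), " was assayed in a routine laboratory series."),
             concepts = b, iw = FALSE)
      )
      add_record(maybe_noise_mesh(b), sents, pick_year())
    }
  }

  # too-general decoys: MeSH-only with C, plus inflated DF via noise records
  for (b in spec$too_general_b) {
    for (k in seq_len(spec$c_per_decoy)) {
      sents <- list(
        title_sentence(),
        list(text = paste0("Patients with ", cpt, " were examined."),
             concepts = cpt, iw = FALSE)
      )
      add_record(c(cpt, b), sents, pick_year())
    }
  }

  # --- A literature: targets reachable only via relevant linking concepts ---
  for (a in spec$targets) {
    for (b in spec$relevant_b) {
      for (k in seq_len(spec$a_per_link)) {
        use_iw <- rng$runif(1) < spec$interaction_rate
        if (use_iw) {
          verb <- rng$sample(verbs, 1L)
          sents <- list(
            title_sentence(),
            list(text = paste0(.cap(b), " ", verb, " ", a, " levels in serum."),
                 concepts = c(b, a), iw = TRUE)
          )
        } else {
          sents <- list(
            title_sentence(),
            list(text = paste0(.cap(b), " was measured in plasma samples."),
                 concepts = b, iw = FALSE),
            list(text = "Assay conditions were standardized.",
                 concepts = character(), iw = FALSE),
            list(text = paste0(.cap(a), " readings were also recorded."),
                 concepts = a, iw = FALSE)
          )
        }
        add_record(c(b, a), sents, pick_year())
      }
    }
  }

  # --- background noise ------------------------------------------------------
  n_noise <- spec$n_records - length(records)
  for (k in seq_len(n_noise)) {
    mesh <- rng$sample(noise_vocab, 2L)
    if (length(spec$too_general_b) > 0L && rng$runif(1) < 0.8) {
      mesh <- c(mesh, rng$sample(spec$too_general_b, 1L))
    }
    sents <- list(
      title_sentence(),
      list(text = "Routine laboratory assays were performed on archived samples.",
           concepts = character(), iw = FALSE)
    )
    add_record(mesh, sents, pick_year())
  }

  # the ABC constraint: no record may contain both C and a target
  for (entry in log) {
    all_con <- unique(c(entry$mesh,
                        unlist(lapply(entry$sentences, function(s) s$concepts))))
    if (cpt %in% all_con && length(intersect(spec$targets, all_con)) > 0L) {
      stop("internal generator error: C and a target share record ",
           entry$pmid, call. = FALSE)
    }
  }

  decoy_kinds <- vapply(seq_along(spec$decoy_b), decoy_kind, character(1))
  labels <- data.frame(
    concept = c(spec$relevant_b, spec$decoy_b, spec$too_general_b),
    role = c(rep("relevant", length(spec$relevant_b)),
             rep("decoy", length(spec$decoy_b) + length(spec$too_general_b))),
    kind = c(rep("interaction_with_start", length(spec$relevant_b)),
             decoy_kinds, rep("too_general", length(spec$too_general_b))),
    stringsAsFactors = FALSE
  )
  truth <- list(spec = spec, plant_log = log, labels = labels,
                start = cpt, targets = spec$targets,
                relevant_b = spec$relevant_b,
                decoy_b = c(spec$decoy_b, spec$too_general_b),
                noise_vocab = noise_vocab)
  list(records = structure(records, class = "medline_corpus"), truth = truth)
}

#' Expected occurrence and co-occurrence counts from the plant log
#'
#' Aggregates the generator's per-sentence plant log into the document-level
#' counts a [build_index()] over the generated corpus must reproduce. The
#' aggregation walks the log directly (simple loops over planted concept
#' sets) and never touches the rendered text, so it is an independent check
#' on parsing, segmentation and mention finding.
#'
#' @param truth the `truth` component of [generate_corpus()] output.
#' @param scope one of `"mesh_field"`, `"tiab"`, `"sentence"`, `"window"`.
#' @return list with `n_docs`, `occ` (named integer), `cooc` (data.frame
#'   `a`, `b`, `n` with `a < b`).
#' @export
planted_counts <- function(truth, scope) {
  stopifnot(scope %in% .index_scopes)
  occ <- list(); pairs_a <- character(); pairs_b <- character()
  for (entry in truth$plant_log) {
    if (scope == "mesh_field") {
      present <- entry$mesh
      if (length(present)) occ[[length(occ) + 1L]] <- present
      if (length(present) >= 2L) {
        cmb <- utils::combn(sort(present), 2L)
        pairs_a <- c(pairs_a, cmb[1L, ]); pairs_b <- c(pairs_b, cmb[2L, ])
      }
      next
    }
    sent_sets <- lapply(entry$sentences, function(s) s$concepts)
    present <- unique(unlist(sent_sets, use.names = FALSE))
    if (length(present)) occ[[length(occ) + 1L]] <- present
    if (length(present) < 2L) next
    present <- sort(present)
    where <- lapply(present, function(con) {
      which(vapply(sent_sets, function(s) con %in% s, logical(1))) - 1L
    })
    for (i in seq_len(length(present) - 1L)) {
      for (j in seq(i + 1L, length(present))) {
        d <- min(abs(outer(where[[i]], where[[j]], "-")))
        ok <- switch(scope, tiab = TRUE, sentence = d == 0L, window = d <= 1L)
        if (ok) {
          pairs_a <- c(pairs_a, present[i]); pairs_b <- c(pairs_b, present[j])
        }
      }
    }
  }
  occ_tab <- table(unlist(occ, use.names = FALSE))
  cooc <- if (length(pairs_a)) {
    agg <- stats::aggregate(list(n = rep(1L, length(pairs_a))),
                            by = list(a = pairs_a, b = pairs_b), FUN = sum)
    agg[order(agg$a, agg$b), , drop = FALSE]
  } else {
    data.frame(a = character(), b = character(), n = integer())
  }
  list(n_docs = length(truth$plant_log),
       occ = stats::setNames(as.integer(occ_tab), names(occ_tab)),
       cooc = cooc)
}

#' Semantic-type map for a synthetic corpus
#'
#' Relevant and decoy linking concepts cycle through the nine linking
#' semantic types, targets cycle through the five target types, the
#' starting concept is a `Disease or Syndrome`, and noise vocabulary gets
#' non-linking, non-target types — so every planted target passes the
#' target-type filter and every noise concept fails both filters.
#'
#' @param spec a [corpus_spec()].
#' @return a `semantic_type_map`.
#' @export
generate_semantic_types <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  map <- list()
  assign_cycle <- function(concepts, types) {
    for (i in seq_along(concepts)) {
      map[[concepts[i]]] <<- union(map[[concepts[i]]],
                                   types[(i - 1L) %% length(types) + 1L])
    }
  }
  map[[spec$start_concept]] <- "Disease or Syndrome"
  assign_cycle(c(spec$relevant_b, spec$decoy_b, spec$too_general_b),
               linking_semantic_types())
  assign_cycle(spec$targets, target_semantic_types())
  assign_cycle(sprintf("noisec%02d", 1:15),
               c("Pharmacologic Substance", "Body Part", "Laboratory Procedure"))
  structure(map, class = "semantic_type_map")
}

#' Serialize ground truth as JSON
#'
#' @param truth the `truth` component of [generate_corpus()] output.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  out <- list(
    start = truth$start, targets = truth$targets,
    relevant_b = truth$relevant_b, decoy_b = truth$decoy_b,
    labels = truth$labels,
    plant_log = lapply(truth$plant_log, function(e) {
      list(pmid = e$pmid, year = e$year, mesh = e$mesh,
           sentences = lapply(e$sentences, function(s)
             list(concepts = s$concepts, iw = s$iw)))
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
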
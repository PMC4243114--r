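#' Discover target concepts from positive linking concepts
#'
#' Target candidates are concepts co-occurring (MeSH field) with at least
#' one positive linking concept. Excluded: the starting concept itself;
#' concepts co-occurring with the starting concept (the ABC model's
#' no-direct-link constraint, evaluated in the MeSH-field scope); concepts
#' already in the preliminary linking set; and, when the type filter is
#' enabled, concepts outside the target semantic types.
#'
#' @param positive_b character vector of positive linking concepts.
#' @param mesh_index `cooc_index` at scope `mesh_field`.
#' @param preliminary_b the full preliminary linking set (superset of
#'   `positive_b`).
#' @param start the starting concept C.
#' @param type_map optional `semantic_type_map`.
#' @param type_filter optional [type_filter_config()].
#' @return named list: target concept -> character vector of linking
#'   concepts (the positive B's co-occurring with it).
#' @export
discover_targets <- function(positive_b, mesh_index, preliminary_b, start,
                             type_map = NULL, type_filter = NULL) {
  start <- normalize_concept(start)
  positive_b <- normalize_concept(positive_b)
  preliminary_b <- normalize_concept(preliminary_b)
  if (length(positive_b) == 0L) {
    warning("no positive linking concepts; no targets discoverable",
            call. = FALSE)
    return(stats::setNames(list(), character()))
  }
  links <- list()
  for (b in positive_b) {
    for (a in names(cooc_partners(mesh_index, b))) {
      links[[a]] <- union(links[[a]], b)
    }
  }
  cands <- setdiff(names(links), c(start, preliminary_b))
  cands <- cands[vapply(cands, function(a) cooc_count(mesh_index, a, start) == 0L,
                        logical(1))]
  if (!is.null(type_filter) && isTRUE(type_filter$enabled) && !is.null(type_map)) {
    cands <- cands[vapply(cands, function(a) has_type(type_map, a, type_filter$target_types),
                          logical(1))]
  }
  links[sort(cands)]
}

#' Useful linking concepts for one target under a ranking rule
#'
#' `plain_ltc` keeps the whole linking set; `rule1` keeps linking concepts
#' co-occurring with the target in the title+abstract text of some record;
#' `rule2` (stricter) keeps those sharing a single sentence with the target
#' where that sentence also contains an interaction word.
#'
#' @param target the target concept A.
#' @param linking character vector of linking concepts connected to A.
#' @param rule one of `"plain_ltc"`, `"rule1"`, `"rule2"`.
#' @param scan a [scan_corpus()] result covering linking and target concepts.
#' @param lexicon an `interaction_lexicon` (required for `rule2`).
#' @return character vector, the useful subset of `linking`.
#' @export
useful_linking_set <- function(target, linking, rule, scan, lexicon = NULL) {
  rule <- match.arg(rule, c("plain_ltc", "rule1", "rule2"))
  target <- normalize_concept(target)
  linking <- normalize_concept(linking)
  if (rule == "plain_ltc" || length(linking) == 0L) return(linking)
  if (rule == "rule2" && (is.null(lexicon) || length(lexicon$words) == 0L)) {
    stop("rule2 requires a non-empty interaction lexicon", call. = FALSE)
  }
  keep <- logical(length(linking))
  for (entry in scan) {
    men <- entry$mentions
    si_t <- men$sentence_index[men$concept == target]
    if (length(si_t) == 0L) next
    iw <- NULL
    for (k in seq_along(linking)) {
      if (keep[k]) next
      si_b <- men$sentence_index[men$concept == linking[k]]
      if (length(si_b) == 0L) next
      if (rule == "rule1") {
        keep[k] <- TRUE
      } else {
        shared <- intersect(si_t, si_b)
        if (length(shared) == 0L) next
        if (is.null(iw)) {
          iw <- vapply(entry$sentences$text, contains_interaction_word,
                       logical(1), lex = lexicon)
          names(iw) <- NULL
        }
        if (any(iw[match(shared, entry$sentences$index)])) keep[k] <- TRUE
      }
    }
    if (all(keep)) break
  }
  linking[keep]
}

#' Dense-rank targets by useful linking-term count
#'
#' Sorts by `useful_ltc` descending with dense ranking: equal counts share a
#' rank and the next distinct count gets the next integer rank; within a
#' rank, targets are listed alphabetically.
#'
#' @param targets `data.frame` with columns `concept` and `useful_ltc`
#'   (and optionally `ltc`).
#' @return the `data.frame` sorted, with a `rank` column added.
#' @export
rank_targets <- function(targets) {
  if (nrow(targets) == 0L) {
    targets$rank <- integer()
    return(targets)
  }
  ord <- order(-targets$useful_ltc, targets$concept)
  out <- targets[ord, , drop = FALSE]
  counts <- out$useful_ltc
  out$rank <- cumsum(!duplicated(counts))
  rownames(out) <- NULL
  out
}

#' Dense rank restricted to targets of given semantic types
#'
#' @param ranked output of [rank_targets()].
#' @param type_map a `semantic_type_map`.
#' @param types character vector of semantic-type names defining the group.
#' @return `ranked` subset to the group, re-ranked densely in a `type_rank`
#'   column.
#' @export
rank_in_types <- function(ranked, type_map, types) {
  keep <- vapply(ranked$concept, function(a) has_type(type_map, a, types),
                 logical(1))
  sub <- ranked[keep, , drop = FALSE]
  if (nrow(sub) == 0L) {
    sub$type_rank <- integer()
    return(sub)
  }
  sub$type_rank <- cumsum(!duplicated(sub$useful_ltc))
  rownames(sub) <- NULL
  sub
}

#' Percentage of useful linking-term count
#'
#' `100 * n_useful / n_all`, the evaluation metric for linking-concept
#' pruning.
#'
#' @param n_useful number of useful linking terms.
#' @param n_all number of all linking terms (>= 1).
#' @return the percentage (0-100).
#' @export
#' @examples
#' percent_useful_ltc(148, 1852)  # 8.0 (to one decimal)
percent_useful_ltc <- function(n_useful, n_all) {
  if (n_all < 1) stop("n_all must be >= 1", call. = FALSE)
  if (n_useful < 0 || n_useful > n_all) {
    stop("need 0 <= n_useful <= n_all", call. = FALSE)
  }
  100 * n_useful / n_all
}

#' Discovery-run configuration
#'
#' @param start starting concept C.
#' @param max_year strict publication-year bound (`Inf` = no bound).
#' @param rule ranking rule: `"plain_ltc"`, `"rule1"` or `"rule2"`.
#' @param type_filter a [type_filter_config()].
#' @param use_classifier filter linking concepts with the trained classifier
#'   (`FALSE` gives the "all" configurations).
#' @param designated_target optional known target whose rank is reported.
#' @param seed integer seed for training-set balancing.
#' @param cost classifier cost parameter.
#' @return a `discovery_config` list.
#' @export
discovery_config <- function(start, max_year = Inf, rule = "rule2",
                             type_filter = type_filter_config(enabled = FALSE),
                             use_classifier = TRUE,
                             designated_target = NULL, seed = 1L, cost = 1) {
  rule <- match.arg(rule, c("plain_ltc", "rule1", "rule2"))
  structure(list(start = normalize_concept(start), max_year = max_year,
                 rule = rule, type_filter = type_filter,
                 use_classifier = isTRUE(use_classifier),
                 designated_target = if (is.null(designated_target)) NULL
                                     else normalize_concept(designated_target),
                 seed = as.integer(seed), cost = cost),
            class = "discovery_config")
}

#' Run the open-discovery pipeline C -> B -> A
#'
#' Executes: year filter, candidate linking-concept collection (MeSH
#' co-occurrence with C, optionally type-filtered), feature extraction,
#' classifier filtering (or pass-through), target discovery with pruning,
#' useful-linking-set computation under the configured rule, dense ranking,
#' and the percentage-of-useful-LTC evaluation (`n_useful` = linking
#' concepts useful for at least one discovered target, `n_all` = linking
#' concepts used for discovery).
#'
#' @param config a [discovery_config()].
#' @param records corpus as a list of [medline_record()] objects.
#' @param lexicon an `interaction_lexicon`.
#' @param type_map optional `semantic_type_map`.
#' @param model optional pre-trained `linking_classifier`; when absent and
#'   `use_classifier` is `TRUE`, one is trained on the corpus via
#'   [build_training_set()].
#' @return an `lbd_discovery` list: `linking` (data.frame of candidates,
#'   labels, features), `targets` (ranked data.frame with per-target
#'   linking/useful sets), `evaluation` (n_useful, n_all, percentage,
#'   designated_rank), `model`, `scan`, `indices`.
#' @export
run_open_discovery <- function(config, records, lexicon, type_map = NULL,
                               model = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  records <- stage("filter_by_year", filter_by_year(records, config$max_year))
  if (length(records) == 0L) stop("stage 'filter_by_year': empty corpus", call. = FALSE)
  mesh_index <- stage("index_mesh", build_index(records, "mesh_field"))
  preliminary <- stage("candidate_linking_concepts",
                       candidate_linking_concepts(mesh_index, config$start,
                                                  type_map, config$type_filter))
  all_concepts <- unique(c(config$start, names(mesh_index$occ)))
  scan <- stage("scan_corpus", scan_corpus(records, all_concepts))
  indices <- list(
    mesh_field = mesh_index,
    tiab = stage("index_tiab", build_index(records, "tiab", scan = scan)),
    sentence = stage("index_sentence", build_index(records, "sentence", scan = scan)),
    window = stage("index_window", build_index(records, "window", scan = scan))
  )
  feats <- stage("extract_features",
                 feature_matrix(config$start, preliminary, indices, scan, lexicon))

  if (config$use_classifier) {
    if (is.null(model)) {
      training <- stage("build_training_set",
                        build_training_set(feats, mesh_index, seed = config$seed))
      model <- stage("train", train_linking_classifier(training,
                                                       cost = config$cost,
                                                       seed = config$seed))
    }
    labels <- stage("classify", classify_linking(model, feats))
  } else {
    labels <- rep("positive", nrow(feats))
  }
  feats$label <- labels
  positive_b <- feats$concept[labels == "positive"]

  targets <- stage("discover_targets",
                   discover_targets(positive_b, mesh_index, preliminary,
                                    config$start, type_map, config$type_filter))
  tdf <- data.frame(concept = names(targets),
                    ltc = lengths(targets), stringsAsFactors = FALSE)
  useful_sets <- lapply(names(targets), function(a) {
    stage("useful_linking_set",
          useful_linking_set(a, targets[[a]], config$rule, scan, lexicon))
  })
  names(useful_sets) <- names(targets)
  tdf$useful_ltc <- lengths(useful_sets)
  ranked <- stage("rank_targets", rank_targets(tdf))

  n_all <- length(positive_b)
  useful_union <- unique(unlist(useful_sets, use.names = FALSE))
  n_useful <- length(intersect(positive_b, useful_union))
  evaluation <- list(
    n_useful = n_useful, n_all = n_all,
    percentage = if (n_all >= 1) percent_useful_ltc(n_useful, n_all) else NA_real_,
    designated_rank = if (!is.null(config$designated_target) &&
                          config$designated_target %in% ranked$concept) {
      ranked$rank[ranked$concept == config$designated_target]
    } else NA_integer_
  )
  structure(list(config = config, linking = feats, targets = ranked,
                 linking_sets = targets, useful_sets = useful_sets,
                 evaluation = evaluation, model = model,
                 scan = scan, indices = indices),
            class = "lbd_discovery")
}

#' @export
print.lbd_discovery <- function(x, ...) {
  ev <- x$evaluation
  cat("<lbd_discovery start='", x$config$start, "' rule=", x$config$rule,
      " classifier=", x$config$use_classifier, ">\n", sep = "")
  cat("  linking concepts: ", ev$n_all, " (of ", nrow(x$linking),
      " candidates)\n", sep = "")
  cat("  targets: ", nrow(x$targets), "\n", sep = "")
  cat("  useful LTC: ", ev$n_useful, "/", ev$n_all, " = ",
      sprintf("%.1f%%", ev$percentage), "\n", sep = "")
  if (!is.na(ev$designated_rank)) {
    cat("  rank of '", x$config$designated_target, "': ", ev$designated_rank,
        "\n", sep = "")
  }
  if (nrow(x$targets)) print(utils::head(x$targets, 10))
  invisible(x)
}

#' Evaluate linking concepts against a designated target
#'
#' Evaluation modes for feature-ablation style experiments:
#' `mesh_vs_designated` counts a linking concept useful iff it co-occurs
#' with the designated target in the MeSH field; `rule1`/`rule2` use the
#' textual-evidence rules of [useful_linking_set()].
#'
#' @param linking character vector of linking concepts under evaluation.
#' @param designated_target the known target concept.
#' @param mode `"mesh_vs_designated"`, `"rule1"` or `"rule2"`.
#' @param mesh_index `cooc_index` at scope `mesh_field`.
#' @param scan a [scan_corpus()] result (for the textual modes).
#' @param lexicon an `interaction_lexicon` (for `rule2`).
#' @return list with `n_useful`, `n_all`, `percentage`, `useful` (the
#'   useful subset).
#' @export
evaluate_linking <- function(linking, designated_target, mode, mesh_index = NULL,
                             scan = NULL, lexicon = NULL) {
  mode <- match.arg(mode, c("mesh_vs_designated", "rule1", "rule2"))
  linking <- normalize_concept(linking)
  a <- normalize_concept(designated_target)
  useful <- if (mode == "mesh_vs_designated") {
    if (is.null(mesh_index)) stop("mesh_vs_designated needs mesh_index", call. = FALSE)
    linking[vapply(linking, function(b) cooc_count(mesh_index, a, b) >= 1L,
                   logical(1))]
  } else {
    useful_linking_set(a, linking, mode, scan, lexicon)
  }
  list(n_useful = length(useful), n_all = length(linking),
       percentage = if (length(linking) >= 1) percent_useful_ltc(length(useful), length(linking)) else NA_real_,
       useful = useful)
}
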
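#' Mutual Information Measure between two concepts
#'
#' `MIM(A, B) = log2( P_AB / (P_A * P_B) )` where probabilities are document
#' frequencies over a corpus of `n_docs` records. When the joint or either
#' marginal count is zero the score is undefined; a configurable floor
#' (default -20 bits) is substituted so feature vectors stay finite.
#'
#' @param n_ab number of records where A and B co-occur.
#' @param n_a,n_b marginal document counts.
#' @param n_docs corpus size (>= 1).
#' @param floor value returned when the score is undefined.
#' @return the MIM score in bits.
#' @export
#' @examples
#' mim(2, 2, 2, 8)   # 2 bits
#' mim(1, 2, 2, 4)   # independence: 0 bits
mim <- function(n_ab, n_a, n_b, n_docs, floor = -20) {
  if (n_docs < 1L) stop("n_docs must be >= 1", call. = FALSE)
  if (n_ab < 0 || n_a < 0 || n_b < 0 || n_ab > min(n_a, n_b) ||
      max(n_a, n_b) > n_docs) {
    stop("invalid counts: need 0 <= n_ab <= min(n_a, n_b) <= n_docs",
         call. = FALSE)
  }
  if (n_ab == 0 || n_a == 0 || n_b == 0) return(floor)
  log2((n_ab * n_docs) / (n_a * n_b))
}

.feature_names <- c("f1", "f2", "f3", "f4", "f5", "f6", "f7")

#' Extract the seven-dimensional feature vector for a concept pair
#'
#' Features: I/II are MIM scores over the MeSH-field and title+abstract
#' scopes; III = 1 iff some sentence mentions both concepts; IV = 1 iff such
#' a sentence also contains an interaction word; V = 1 iff two sentences at
#' index distance <= 1 (a single sentence counts) cover both; VI = 1 iff
#' some such window also contains an interaction word anywhere within it;
#' VII = 1 iff both are mentioned in the abstract text of some record (the
#' loose reading; `strict_f7 = TRUE` additionally requires no window-level
#' co-occurrence, i.e. the pair co-occurs *only* at abstract distance).
#'
#' @param start the starting concept C.
#' @param concept the linking-candidate concept B.
#' @param indices named list of `cooc_index` objects with elements
#'   `mesh_field` and `tiab` (from [build_index()]).
#' @param scan a [scan_corpus()] result covering both concepts.
#' @param lexicon an `interaction_lexicon`.
#' @param mim_floor floor for undefined MIM scores.
#' @param strict_f7 use the strict "only in abstract" reading of feature VII.
#' @return one-row `data.frame` with columns `starting`, `concept`,
#'   `f1`...`f7`.
#' @export
extract_features <- function(start, concept, indices, scan, lexicon,
                             mim_floor = -20, strict_f7 = FALSE) {
  start <- normalize_concept(start)
  concept <- normalize_concept(concept)
  mi <- function(index) {
    mim(cooc_count(index, start, concept), occ_count(index, start),
        occ_count(index, concept), index$n_docs, floor = mim_floor)
  }
  f1 <- mi(indices$mesh_field)
  f2 <- mi(indices$tiab)

  f3 <- 0L; f4 <- 0L; f5 <- 0L; f6 <- 0L; f7 <- 0L
  for (entry in scan) {
    men <- entry$mentions
    si_a <- men$sentence_index[men$concept == start]
    si_b <- men$sentence_index[men$concept == concept]
    if (length(si_a) == 0L || length(si_b) == 0L) next
    sents <- entry$sentences
    has_iw <- vapply(sents$text, contains_interaction_word, logical(1),
                     lex = lexicon)
    names(has_iw) <- NULL
    shared <- intersect(si_a, si_b)
    if (length(shared) > 0L) {
      f3 <- 1L; f5 <- 1L
      if (any(has_iw[match(shared, sents$index)])) { f4 <- 1L; f6 <- 1L }
    }
    for (i in unique(si_a)) {
      for (j in unique(si_b)) {
        if (abs(i - j) > 1L) next
        f5 <- 1L
        if (any(has_iw[match(unique(c(i, j)), sents$index)])) f6 <- 1L
      }
    }
    ab_idx <- sents$index[sents$source == "abstract"]
    if (any(si_a %in% ab_idx) && any(si_b %in% ab_idx)) f7 <- 1L
  }
  if (strict_f7 && f5 == 1L) f7 <- 0L
  data.frame(starting = start, concept = concept,
             f1 = f1, f2 = f2, f3 = f3, f4 = f4, f5 = f5, f6 = f6, f7 = f7,
             stringsAsFactors = FALSE)
}

#' Feature matrix for many linking-concept candidates
#'
#' @param start the starting concept C.
#' @param concepts character vector of candidate linking concepts.
#' @inheritParams extract_features
#' @return `data.frame` with one row per candidate.
#' @export
feature_matrix <- function(start, concepts, indices, scan, lexicon,
                           mim_floor = -20, strict_f7 = FALSE) {
  rows <- lapply(concepts, function(b) {
    extract_features(start, b, indices, scan, lexicon,
                     mim_floor = mim_floor, strict_f7 = strict_f7)
  })
  if (length(rows) == 0L) {
    return(data.frame(starting = character(), concept = character(),
                      f1 = numeric(), f2 = numeric(), f3 = integer(),
                      f4 = integer(), f5 = integer(), f6 = integer(),
                      f7 = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Write / read a feature matrix as TSV
#'
#' Header columns: `starting`, `concept`, `f1`...`f7`, optional `label`.
#'
#' @param features a feature `data.frame` (optionally with a `label` column).
#' @param path optional output file.
#' @return lines or (for `read_feature_matrix`) a `data.frame`.
#' @export
write_feature_matrix <- function(features, path = NULL) {
  lines <- c(paste(names(features), collapse = "\t"),
             do.call(paste, c(unname(as.list(features)), sep = "\t")))
  if (nrow(features) == 0L) lines <- lines[1]
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @rdname write_feature_matrix
#' @param x file path, string, or character lines.
#' @export
read_feature_matrix <- function(x) {
  lines <- .as_lines(x)
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE)
  for (col in intersect(.feature_names, names(df))) df[[col]] <- as.numeric(df[[col]])
  df
}
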
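#' Scan a corpus for sentences and concept mentions
#'
#' Runs [segment_sentences()] and [find_mentions()] over every record once,
#' so the four co-occurrence scopes and the textual features can share the
#' same mention data.
#'
#' @param records a list of [medline_record()] objects.
#' @param concepts character vector of concept strings (normalized
#'   internally).
#' @return a `corpus_scan`: a named (by pmid) list with elements `pmid`,
#'   `sentences`, `mentions` per record.
#' @export
scan_corpus <- function(records, concepts) {
  concepts <- unique(normalize_concept(concepts))
  concepts <- concepts[nzchar(concepts)]
  scans <- lapply(records, function(r) {
    sents <- segment_sentences(r)
    list(pmid = r$pmid, sentences = sents,
         mentions = find_mentions(r, concepts, sents))
  })
  names(scans) <- vapply(records, function(r) r$pmid, character(1))
  structure(scans, concepts = concepts, class = "corpus_scan")
}

.index_scopes <- c("mesh_field", "tiab", "sentence", "window")

# concepts present in a record at the given scope, plus co-occurring pairs
.record_presence <- function(record, scan_entry, scope, concepts) {
  if (scope == "mesh_field") {
    present <- record$mesh_terms
    if (!is.null(concepts)) present <- intersect(present, concepts)
    pairs <- if (length(present) >= 2L) utils::combn(sort(present), 2L) else NULL
    return(list(present = present, pairs = pairs))
  }
  men <- scan_entry$mentions
  present <- unique(men$concept)
  if (length(present) < 2L) {
    return(list(present = present, pairs = NULL))
  }
  if (scope == "tiab") {
    pairs <- utils::combn(sort(present), 2L)
    return(list(present = present, pairs = pairs))
  }
  idx <- split(men$sentence_index, men$concept)
  present <- sort(present)
  keep_a <- character(); keep_b <- character()
  for (i in seq_len(length(present) - 1L)) {
    for (j in seq(i + 1L, length(present))) {
      di <- idx[[present[i]]]; dj <- idx[[present[j]]]
      dist <- min(abs(outer(di, dj, "-")))
      ok <- if (scope == "sentence") dist == 0L else dist <= 1L
      if (ok) { keep_a <- c(keep_a, present[i]); keep_b <- c(keep_b, present[j]) }
    }
  }
  pairs <- if (length(keep_a)) rbind(keep_a, keep_b) else NULL
  list(present = present, pairs = pairs)
}

#' Build a concept co-occurrence index
#'
#' Counts, per concept and per unordered concept pair, the number of records
#' where they occur (jointly) at the requested scope. Counts are
#' document-level: a pair co-occurring in three sentences of one record
#' counts once.
#'
#' Scopes: `mesh_field` (both concepts in the MH list), `tiab` (both
#' mentioned anywhere in title + abstract), `sentence` (some single sentence
#' mentions both), `window` (some pair of sentences at index distance <= 1
#' covers both; a single sentence qualifies).
#'
#' @param records a list of [medline_record()] objects.
#' @param scope one of `"mesh_field"`, `"tiab"`, `"sentence"`, `"window"`.
#' @param concepts concept strings restricting the index; `NULL` for
#'   `mesh_field` means all MeSH terms. Required for text scopes unless
#'   `scan` is given.
#' @param scan optional precomputed [scan_corpus()] result.
#' @return a `cooc_index`: list with `scope`, `n_docs`, `occ` (named integer
#'   vector), `cooc` (data.table with columns `a`, `b`, `n`, `a < b`).
#' @export
build_index <- function(records, scope, concepts = NULL, scan = NULL) {
  if (!(scope %in% .index_scopes)) {
    stop("unknown scope: ", scope, " (expected one of ",
         paste(.index_scopes, collapse = ", "), ")", call. = FALSE)
  }
  if (!is.null(concepts)) concepts <- unique(normalize_concept(concepts))
  if (scope != "mesh_field" && is.null(scan)) {
    if (is.null(concepts)) {
      stop("text scopes need `concepts` or a precomputed `scan`", call. = FALSE)
    }
    scan <- scan_corpus(records, concepts)
  }
  occ_acc <- list(); pair_acc <- list()
  for (i in seq_along(records)) {
    entry <- if (is.null(scan)) NULL else scan[[i]]
    pres <- .record_presence(records[[i]], entry, scope, concepts)
    if (length(pres$present)) occ_acc[[length(occ_acc) + 1L]] <- pres$present
    if (!is.null(pres$pairs)) {
      pair_acc[[length(pair_acc) + 1L]] <-
        data.table::data.table(a = pres$pairs[1L, ], b = pres$pairs[2L, ])
    }
  }
  occ_tab <- table(unlist(occ_acc, use.names = FALSE))
  occ <- stats::setNames(as.integer(occ_tab), names(occ_tab))
  if (length(pair_acc)) {
    dt <- data.table::rbindlist(pair_acc)
    cooc <- dt[, list(n = .N), by = c("a", "b")]
    data.table::setkeyv(cooc, c("a", "b"))
  } else {
    cooc <- data.table::data.table(a = character(), b = character(),
                                   n = integer())
    data.table::setkeyv(cooc, c("a", "b"))
  }
  structure(list(scope = scope, n_docs = length(records), occ = occ,
                 cooc = cooc),
            class = "cooc_index")
}

#' @export
print.cooc_index <- function(x, ...) {
  cat("<cooc_index scope=", x$scope, " n_docs=", x$n_docs,
      " concepts=", length(x$occ), " pairs=", nrow(x$cooc), ">\n", sep = "")
  invisible(x)
}

#' Query occurrence and co-occurrence counts
#'
#' @param index a `cooc_index`.
#' @param concept,a,b concept strings (normalized internally).
#' @return an integer count (0 for unseen concepts/pairs).
#' @export
occ_count <- function(index, concept) {
  concept <- normalize_concept(concept)
  n <- index$occ[concept]
  if (is.na(n)) 0L else as.integer(n)
}

#' @rdname occ_count
#' @export
cooc_count <- function(index, a, b) {
  a <- normalize_concept(a); b <- normalize_concept(b)
  if (a == b) return(occ_count(index, a))
  key <- sort(c(a, b))
  row <- index$cooc[list(key[1], key[2]), on = c("a", "b"), nomatch = NULL]
  if (nrow(row) == 0L) 0L else as.integer(row$n[1])
}

#' Concepts co-occurring with a given concept
#'
#' @param index a `cooc_index`.
#' @param concept a concept string.
#' @return named integer vector of joint counts, names are the partners.
#' @export
cooc_partners <- function(index, concept) {
  concept <- normalize_concept(concept)
  hits <- index$cooc[index$cooc$a == concept | index$cooc$b == concept, ]
  if (nrow(hits) == 0L) return(stats::setNames(integer(), character()))
  partner <- ifelse(hits$a == concept, hits$b, hits$a)
  stats::setNames(as.integer(hits$n), partner)
}

#' Candidate linking concepts for a starting concept
#'
#' All concepts B != C with `cooc(C, B) >= 1` in the MeSH-field index,
#' optionally restricted to the configured linking semantic types.
#'
#' @param index a `cooc_index` built at scope `mesh_field`.
#' @param start the starting concept C.
#' @param type_map optional `semantic_type_map`.
#' @param type_filter optional [type_filter_config()]; applied only when
#'   `enabled` and `type_map` is given.
#' @return sorted character vector of linking-concept candidates.
#' @export
candidate_linking_concepts <- function(index, start, type_map = NULL,
                                       type_filter = NULL) {
  start <- normalize_concept(start)
  if (occ_count(index, start) == 0L) {
    warning("starting concept '", start, "' absent from corpus", call. = FALSE)
    return(character())
  }
  partners <- names(cooc_partners(index, start))
  partners <- setdiff(partners, start)
  if (!is.null(type_filter) && isTRUE(type_filter$enabled) && !is.null(type_map)) {
    keep <- vapply(partners, function(b) has_type(type_map, b, type_filter$linking_types),
                   logical(1))
    partners <- partners[keep]
  }
  sort(partners)
}

#' Restrict a corpus to records published strictly before a year
#'
#' Replicates the pre-discovery literature window: `year < max_year`.
#' Records without a year are dropped when `max_year` is finite.
#'
#' @param records a list of [medline_record()] objects.
#' @param max_year strict upper bound; `Inf` keeps everything.
#' @return the filtered record list.
#' @export
filter_by_year <- function(records, max_year) {
  if (is.infinite(max_year)) return(records)
  keep <- vapply(records, function(r) !is.na(r$year) && r$year < max_year,
                 logical(1))
  records[keep]
}

#' Serialize / load a co-occurrence index as a 3-section TSV
#'
#' Layout: a header section (`scope`, `n_docs`), an `[occ]` section
#' (`concept<TAB>n`), and a `[cooc]` section (`a<TAB>b<TAB>n`).
#'
#' @param index a `cooc_index`.
#' @param path optional output file.
#' @return `write_index`: the lines (invisibly when `path` given);
#'   `read_index`: a `cooc_index`.
#' @export
write_index <- function(index, path = NULL) {
  lines <- c(paste0("scope\t", index$scope),
             paste0("n_docs\t", index$n_docs),
             "[occ]")
  if (length(index$occ)) {
    ord <- order(names(index$occ))
    lines <- c(lines, paste(names(index$occ)[ord], index$occ[ord], sep = "\t"))
  }
  lines <- c(lines, "[cooc]")
  if (nrow(index$cooc)) {
    lines <- c(lines, paste(index$cooc$a, index$cooc$b, index$cooc$n, sep = "\t"))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @rdname write_index
#' @param x file path, string, or character lines.
#' @export
read_index <- function(x) {
  lines <- .as_lines(x)
  scope <- sub("^scope\t", "", lines[1])
  n_docs <- as.integer(sub("^n_docs\t", "", lines[2]))
  occ_start <- which(lines == "[occ]")
  cooc_start <- which(lines == "[cooc]")
  occ_lines <- lines[seq_len(cooc_start - occ_start - 1L) + occ_start]
  occ <- stats::setNames(integer(), character())
  if (length(occ_lines)) {
    parts <- do.call(rbind, strsplit(occ_lines, "\t", fixed = TRUE))
    occ <- stats::setNames(as.integer(parts[, 2]), parts[, 1])
  }
  cooc_lines <- if (cooc_start < length(lines)) lines[(cooc_start + 1L):length(lines)] else character()
  if (length(cooc_lines)) {
    parts <- do.call(rbind, strsplit(cooc_lines, "\t", fixed = TRUE))
    cooc <- data.table::data.table(a = parts[, 1], b = parts[, 2],
                                   n = as.integer(parts[, 3]))
  } else {
    cooc <- data.table::data.table(a = character(), b = character(), n = integer())
  }
  data.table::setkeyv(cooc, c("a", "b"))
  structure(list(scope = scope, n_docs = n_docs, occ = occ, cooc = cooc),
            class = "cooc_index")
}
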
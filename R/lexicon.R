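#' Default semantic-type sets
#'
#' The nine semantic types used to filter linking concepts (disease-function
#' types) and the five dietary-factor types used to filter target concepts,
#' following the classic Raynaud/migraine open-discovery setups.
#'
#' @name semantic_type_sets
#' @export
linking_semantic_types <- function() {
  c("Biological function", "Cell function", "Finding", "Molecular function",
    "Organism function", "Organ or Tissue function", "Pathological function",
    "Phenomenon or process", "Physiological function")
}

#' @rdname semantic_type_sets
#' @export
target_semantic_types <- function() {
  c("Element", "Ion", "Isotope", "Vitamin", "Lipid")
}

# the portion of the 135-name semantic-type universe this package uses; the
# full UMLS Semantic Network list is not shipped, unknown names load with a
# warning
.known_semantic_types <- function() {
  c(linking_semantic_types(), target_semantic_types(),
    "Disease or Syndrome", "Pharmacologic Substance", "Body Part",
    "Chemical", "Gene or Genome", "Cell", "Tissue", "Organism",
    "Laboratory Procedure", "Sign or Symptom", "Mental Process",
    "Amino Acid", "Carbohydrate", "Hormone", "Enzyme", "Protein")
}

#' Type-filter configuration
#'
#' @param linking_types semantic types admissible for linking concepts.
#' @param target_types semantic types admissible for target concepts.
#' @param enabled logical; when `FALSE` no semantic filtering is applied
#'   (the "all" configurations; `TRUE` gives the "+ST" configurations).
#' @return a list of class `type_filter_config`.
#' @export
type_filter_config <- function(linking_types = linking_semantic_types(),
                               target_types = target_semantic_types(),
                               enabled = TRUE) {
  structure(list(linking_types = linking_types, target_types = target_types,
                 enabled = isTRUE(enabled)),
            class = "type_filter_config")
}

#' Load a concept-to-semantic-type mapping
#'
#' Reads a two-column tab-separated file (`concept<TAB>type`); repeated
#' concept lines union their types. Concepts are normalized with
#' [normalize_concept()]. Lines with an unknown type name load with a
#' warning; malformed lines are an error naming the line number.
#'
#' @param x file path, single string with newlines, or character lines.
#' @return a named list mapping concept -> character vector of types, with
#'   class `semantic_type_map`.
#' @export
load_semantic_types <- function(x) {
  lines <- .as_lines(x)
  map <- list()
  known <- .known_semantic_types()
  unknown <- character()
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line)) || grepl("^#", line)) next
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2L || !nzchar(trimws(parts[1])) || !nzchar(trimws(parts[2]))) {
      stop("malformed semantic-type line ", i, ": ", line, call. = FALSE)
    }
    concept <- normalize_concept(parts[1])
    type <- trimws(parts[2])
    if (!(type %in% known)) unknown <- c(unknown, type)
    map[[concept]] <- union(map[[concept]], type)
  }
  if (length(unknown) > 0L) {
    warning("unknown semantic type name(s): ",
            paste(unique(unknown), collapse = ", "), call. = FALSE)
  }
  structure(map, class = "semantic_type_map")
}

#' Write a semantic-type map to the two-column TSV format
#'
#' @param map a `semantic_type_map`.
#' @param path optional output file.
#' @return the lines, invisibly when `path` is given.
#' @export
write_semantic_types <- function(map, path = NULL) {
  lines <- unlist(lapply(sort(names(map)), function(con) {
    paste(con, sort(map[[con]]), sep = "\t")
  }), use.names = FALSE)
  if (is.null(lines)) lines <- character()
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Test semantic-type membership
#'
#' `TRUE` iff `concept` is in the map and its assigned types intersect
#' `types`; concepts absent from the map are `FALSE`.
#'
#' @param map a `semantic_type_map`.
#' @param concept a concept string (normalized internally).
#' @param types character vector of type names.
#' @return logical scalar.
#' @export
has_type <- function(map, concept, types) {
  assigned <- map[[normalize_concept(concept)]]
  if (is.null(assigned)) return(FALSE)
  length(intersect(assigned, types)) > 0L
}

#' Default interaction-word seed lexicon
#'
#' A documented seed list of interaction verbs and inflectional variants
#' (increase, decrease, inhibit, induce, aggravate, reduce, promote, block,
#' stimulate, suppress, ...). The historical 115-entry list is not published;
#' supply a file for replication work.
#'
#' @return an `interaction_lexicon`.
#' @export
default_interaction_lexicon <- function() {
  stems <- c("increase", "decrease", "inhibit", "induce", "aggravate",
             "reduce", "promote", "block", "stimulate", "suppress",
             "activate", "enhance", "prevent", "cause", "elevate")
  variants <- unlist(lapply(stems, function(s) {
    base <- sub("e$", "", s)
    unique(c(s, paste0(s, "s"), paste0(base, "ed"), paste0(base, "ing")))
  }), use.names = FALSE)
  interaction_lexicon(variants)
}

#' Construct or load an interaction-word lexicon
#'
#' @param words character vector of word/variant strings.
#' @return an object of class `interaction_lexicon` (normalized word set).
#' @export
interaction_lexicon <- function(words) {
  words <- unique(tolower(trimws(words)))
  words <- words[nzchar(words)]
  structure(list(words = words), class = "interaction_lexicon")
}

#' @describeIn interaction_lexicon Load a lexicon file: one entry per line,
#'   `#` comments allowed.
#' @param x file path, string, or character lines.
#' @export
load_interaction_lexicon <- function(x) {
  lines <- .as_lines(x)
  lines <- lines[!grepl("^\\s*#", lines)]
  interaction_lexicon(lines)
}

#' Does text contain an interaction word?
#'
#' `TRUE` iff any lexicon entry matches a whole token of `text`,
#' case-insensitively. Tokens are maximal runs of letters/digits/hyphens.
#'
#' @param lex an `interaction_lexicon`.
#' @param text a character string.
#' @return logical scalar.
#' @export
contains_interaction_word <- function(lex, text) {
  if (length(lex$words) == 0L) return(FALSE)
  tokens <- tolower(unlist(strsplit(text, "[^A-Za-z0-9-]+"), use.names = FALSE))
  any(tokens %in% lex$words)
}

#' Load a stop-concept list (one concept per line, `#` comments)
#'
#' @param x file path, string, or character lines.
#' @return character vector of normalized concepts.
#' @export
load_stop_concepts <- function(x) {
  lines <- .as_lines(x)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- normalize_concept(lines)
  unique(lines[nzchar(lines)])
}
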
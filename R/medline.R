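#' Normalize a concept string
#'
#' Lowercases, collapses internal whitespace, strips MeSH qualifier suffixes
#' (everything after the first `/`, e.g. `"Migraine/drug therapy"` ->
#' `"migraine"`) and leading emphasis markers (`*`).
#'
#' @param x character vector of concept strings.
#' @return character vector of normalized concepts.
#' @export
#' @examples
#' normalize_concept("*Migraine/drug therapy")
normalize_concept <- function(x) {
  x <- sub("/.*$", "", x)
  x <- gsub("\\*", "", x)
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Construct a MEDLINE record
#'
#' @param pmid unique record identifier (coerced to character, non-empty).
#' @param title title text.
#' @param abstract abstract text (may be empty).
#' @param mesh_terms character vector of MeSH descriptors; normalized and
#'   de-duplicated, original order kept.
#' @param year publication year (integer >= 1800), or `NA`.
#' @return an object of class `medline_record`.
#' @export
medline_record <- function(pmid, title = "", abstract = "", mesh_terms = character(),
                           year = NA_integer_) {
  pmid <- as.character(pmid)
  if (length(pmid) != 1L || is.na(pmid) || !nzchar(pmid)) {
    stop("pmid must be a single non-empty string", call. = FALSE)
  }
  mesh_terms <- unique(normalize_concept(as.character(mesh_terms)))
  mesh_terms <- mesh_terms[nzchar(mesh_terms)]
  year <- suppressWarnings(as.integer(year))
  if (length(year) != 1L) year <- NA_integer_
  if (!is.na(year) && year < 1800L) {
    stop("year must be >= 1800 (pmid ", pmid, ")", call. = FALSE)
  }
  structure(
    list(pmid = pmid, title = as.character(title)[1L],
         abstract = as.character(abstract)[1L],
         mesh_terms = mesh_terms, year = year),
    class = "medline_record"
  )
}

#' @export
print.medline_record <- function(x, ...) {
  cat("<medline_record ", x$pmid, "> ", x$year, "\n", sep = "")
  cat("  TI: ", x$title, "\n", sep = "")
  if (nzchar(x$abstract)) cat("  AB: ", substr(x$abstract, 1L, 70L), "...\n", sep = "")
  cat("  MH: ", paste(x$mesh_terms, collapse = "; "), "\n", sep = "")
  invisible(x)
}

# split input into lines whether given as path, single string, or line vector
.as_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  # paste-then-split keeps empty lines (record separators) intact
  strsplit(paste(x, collapse = "\n"), "\n", fixed = TRUE)[[1]]
}

#' Parse MEDLINE flat-file records
#'
#' Reads the tag-prefixed MEDLINE dialect: each field line starts with a tag
#' padded to four characters, a hyphen and a space (`"PMID- "`, `"TI  - "`,
#' `"AB  - "`, `"MH  - "`, `"DP  - "`); continuation lines begin with
#' whitespace and are joined with a single space; records are separated by
#' blank lines. Repeated `MH` lines accumulate; qualifier suffixes after `/`
#' and `*` markers are stripped and terms are normalized. The year is the
#' first 4-digit token of the `DP` field.
#'
#' @param x a file path, a single string containing newlines, or a character
#'   vector of lines.
#' @return a list of [medline_record()] objects (class `medline_corpus`).
#' @export
parse_medline <- function(x) {
  lines <- .as_lines(x)
  n <- length(lines)
  records <- list()
  seen <- character()

  flush_block <- function(tags, values, first_line) {
    if (length(tags) == 0L) return(NULL)
    pmid <- values[tags == "PMID"]
    if (length(pmid) == 0L) {
      stop("record block starting at line ", first_line, " has no PMID field",
           call. = FALSE)
    }
    pmid <- trimws(pmid[1L])
    ti <- values[tags == "TI"]
    ab <- values[tags == "AB"]
    dp <- values[tags == "DP"]
    year <- NA_integer_
    if (length(dp) > 0L) {
      tok <- regmatches(dp[1L], regexpr("\\b\\d{4}\\b", dp[1L]))
      if (length(tok) == 1L) year <- as.integer(tok)
    }
    medline_record(
      pmid = pmid,
      title = if (length(ti)) ti[1L] else "",
      abstract = if (length(ab)) ab[1L] else "",
      mesh_terms = values[tags == "MH"],
      year = year
    )
  }

  tags <- character(); values <- character(); first_line <- NA_integer_
  for (i in seq_len(n)) {
    line <- lines[i]
    if (!nzchar(trimws(line))) {
      rec <- flush_block(tags, values, first_line)
      if (!is.null(rec)) {
        if (rec$pmid %in% seen) stop("duplicate PMID: ", rec$pmid, call. = FALSE)
        seen <- c(seen, rec$pmid)
        records[[length(records) + 1L]] <- rec
      }
      tags <- character(); values <- character(); first_line <- NA_integer_
      next
    }
    if (is.na(first_line)) first_line <- i
    m <- regexec("^([A-Z][A-Z0-9]{0,3})\\s*- ", line)[[1]]
    if (m[1] == 1L) {
      tag <- substr(line, m[2], m[2] + attr(m, "match.length")[2] - 1L)
      value <- substr(line, attr(m, "match.length")[1] + 1L, nchar(line))
      tags <- c(tags, tag)
      values <- c(values, value)
    } else if (grepl("^[[:space:]]", line) && length(tags) > 0L) {
      values[length(values)] <- paste(values[length(values)], trimws(line))
    } else {
      stop("malformed line ", i, ": ", line, call. = FALSE)
    }
  }
  rec <- flush_block(tags, values, first_line)
  if (!is.null(rec)) {
    if (rec$pmid %in% seen) stop("duplicate PMID: ", rec$pmid, call. = FALSE)
    records[[length(records) + 1L]] <- rec
  }
  structure(records, class = "medline_corpus")
}

#' Write MEDLINE records as flat-file text
#'
#' Emits the same tag-prefixed dialect [parse_medline()] accepts, with the
#' deterministic field order `PMID`, `DP`, `TI`, `AB`, `MH`...
#'
#' @param records a list of [medline_record()] objects.
#' @param path optional file path; when given, lines are written there.
#' @return invisibly when `path` is given, otherwise a character vector of
#'   lines.
#' @export
write_medline <- function(records, path = NULL) {
  blocks <- lapply(records, function(r) {
    out <- paste0("PMID- ", r$pmid)
    if (!is.na(r$year)) out <- c(out, paste0("DP  - ", r$year))
    if (nzchar(r$title)) out <- c(out, paste0("TI  - ", r$title))
    if (nzchar(r$abstract)) out <- c(out, paste0("AB  - ", r$abstract))
    out <- c(out, paste0("MH  - ", r$mesh_terms))
    out
  })
  lines <- unlist(mapply(function(b, i) if (i < length(blocks)) c(b, "") else b,
                         blocks, seq_along(blocks), SIMPLIFY = FALSE),
                  use.names = FALSE)
  if (is.null(lines)) lines <- character()
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

# tokens before a period that never end a sentence
.sentence_exceptions <- c("vs", "al", "fig", "figs", "no", "dr", "st",
                          "cf", "ca", "approx", "spp")

#' Segment a record into sentences
#'
#' The title is emitted as exactly one sentence with index 0. The abstract is
#' split at terminal punctuation (`.`, `!`, `?`) followed by whitespace and an
#' uppercase letter or digit, except after common abbreviations (`vs.`,
#' `et al.`, `Fig.`, ...) and single-letter initials.
#'
#' @param record a [medline_record()].
#' @return a `data.frame` with columns `record_id`, `index` (0-based,
#'   consecutive), `text`, `source` (`"title"` or `"abstract"`).
#' @export
segment_sentences <- function(record) {
  texts <- record$title
  sources <- "title"
  ab <- record$abstract
  if (!is.na(ab) && nzchar(trimws(ab))) {
    parts <- .split_abstract(ab)
    texts <- c(texts, parts)
    sources <- c(sources, rep("abstract", length(parts)))
  }
  keep <- nzchar(trimws(texts))
  texts <- texts[keep]; sources <- sources[keep]
  data.frame(record_id = rep(record$pmid, length(texts)),
             index = seq_along(texts) - 1L,
             text = texts, source = sources,
             stringsAsFactors = FALSE)
}

.split_abstract <- function(text) {
  m <- gregexpr("[.!?]+(?=[[:space:]]+[\"']?[A-Z0-9])", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(trimws(text))
  cuts <- integer()
  for (k in seq_along(m)) {
    end <- m[k] + attr(m, "match.length")[k] - 1L
    before <- substr(text, 1L, m[k] - 1L)
    tok <- regmatches(before, regexpr("[A-Za-z]+$", before))
    if (length(tok) == 1L) {
      if (nchar(tok) == 1L) {
        # single uppercase letter = an initial; single letter after a
        # period = dotted abbreviation ("e.g.", "i.e."); neither ends a
        # sentence
        prev_pos <- m[k] - 2L
        prev <- if (prev_pos >= 1L) substr(text, prev_pos, prev_pos) else ""
        if (grepl("^[A-Z]$", tok) || prev == ".") next
      } else if (tolower(tok) %in% .sentence_exceptions) next
    }
    cuts <- c(cuts, end)
  }
  if (length(cuts) == 0L) return(trimws(text))
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, nchar(text))
  parts <- substring(text, starts, ends)
  trimws(parts)
}

# word-boundary regex for a normalized concept (whitespace-flexible)
.concept_regex <- function(concept) {
  esc <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", concept)
  esc <- gsub(" ", "[[:space:]]+", esc, fixed = TRUE)
  paste0("(?<![A-Za-z0-9])", esc, "(?![A-Za-z0-9])")
}

#' Find concept mentions in a record
#'
#' Each concept is matched independently, case-insensitively, at word
#' boundaries (so `"ion"` never matches inside `"cation"`); matching
#' concepts independently keeps the result monotone in the concept set.
#' When a matched mention is immediately followed by a parenthesized single
#' token of 1-10 characters (`"Alzheimer's disease (AD)"`), the token is
#' registered as a record-local abbreviation; subsequent whole-token
#' occurrences of it (after the defining parenthesis) yield mentions with
#' `via_abbreviation = TRUE`.
#'
#' @param record a [medline_record()].
#' @param concepts character vector of normalized concept strings
#'   (see [normalize_concept()]).
#' @param sentences optional precomputed [segment_sentences()] output.
#' @return a `data.frame` with columns `concept`, `sentence_index`,
#'   `via_abbreviation`, `start` (match offset within the sentence), one row
#'   per match occurrence, ordered by sentence then offset.
#' @export
find_mentions <- function(record, concepts, sentences = NULL) {
  if (is.null(sentences)) sentences <- segment_sentences(record)
  concepts <- unique(concepts[nzchar(concepts)])
  empty <- data.frame(concept = character(), sentence_index = integer(),
                      via_abbreviation = logical(), start = integer(),
                      stringsAsFactors = FALSE)
  if (length(concepts) == 0L || nrow(sentences) == 0L) return(empty)
  # longer concepts scanned first for a stable, specific-first row order
  concepts <- concepts[order(-nchar(concepts), concepts)]
  regexes <- vapply(concepts, .concept_regex, character(1))

  abbr <- list()  # token -> list(concept, def_sentence, def_end)
  rows <- list()
  for (si in seq_len(nrow(sentences))) {
    s_idx <- sentences$index[si]
    text <- sentences$text[si]
    for (ci in seq_along(concepts)) {
      m <- gregexpr(regexes[ci], text, perl = TRUE, ignore.case = TRUE)[[1]]
      if (m[1] == -1L) next
      for (k in seq_along(m)) {
        rows[[length(rows) + 1L]] <- list(concept = concepts[ci],
                                          sentence_index = s_idx,
                                          via_abbreviation = FALSE,
                                          start = m[k])
        tail_text <- substr(text, m[k] + attr(m, "match.length")[k], nchar(text))
        am <- regexec("^[[:space:]]*\\(([A-Za-z0-9-]{1,10})\\)", tail_text)[[1]]
        if (am[1] == 1L) {
          tok <- substr(tail_text, am[2], am[2] + attr(am, "match.length")[2] - 1L)
          if (is.null(abbr[[tok]])) {
            abbr[[tok]] <- list(concept = concepts[ci], def_sentence = s_idx,
                                def_end = m[k] + attr(m, "match.length")[k] - 1L +
                                  attr(am, "match.length")[1])
          }
        }
      }
    }
    for (tok in names(abbr)) {
      info <- abbr[[tok]]
      pat <- paste0("(?<![A-Za-z0-9])", gsub("([][{}()+*^$|\\\\?.-])", "\\\\\\1", tok),
                    "(?![A-Za-z0-9])")
      m <- gregexpr(pat, text, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      for (k in seq_along(m)) {
        if (s_idx < info$def_sentence) next
        if (s_idx == info$def_sentence && m[k] <= info$def_end) next
        rows[[length(rows) + 1L]] <- list(concept = info$concept,
                                          sentence_index = s_idx,
                                          via_abbreviation = TRUE,
                                          start = m[k])
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(concept = r$concept, sentence_index = r$sentence_index,
               via_abbreviation = r$via_abbreviation, start = r$start,
               stringsAsFactors = FALSE)
  }))
  out[order(out$sentence_index, out$start, out$concept), , drop = FALSE]
}
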
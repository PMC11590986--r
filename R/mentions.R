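#' Compile a dictionary matcher over the protein lexicon
#'
#' The matcher recognises every primary name and synonym, case-insensitively,
#' at alphanumeric word boundaries (a boundary is a transition between
#' `[A-Za-z0-9]` and anything else, or a string edge), so `"RyR2"` matches
#' `"ryr2"` but not inside `"RYR21"`. Overlapping candidate spans are
#' resolved longest-match-first at each position: with both `"troponin"` and
#' `"troponin I"` in the lexicon, `"cardiac troponin I levels"` yields one
#' match for `"troponin I"`. Hyphens and other punctuation inside a synonym
#' match literally.
#'
#' Implemented as a single PCRE alternation with alternatives ordered longest
#' first and lookaround boundary guards; matching scans left to right without
#' overlap, which is the longest-match semantics dictionary NER tools use.
#'
#' @param entities a `protein_entities` table from [load_protein_entities()].
#' @return A `protein_matcher` object.
#' @export
compile_matcher <- function(entities) {
  lexicon <- attr(entities, "lexicon")
  if (is.null(lexicon) || length(lexicon) == 0) {
    stopf("cannot compile a matcher from an empty entity set")
  }
  forms <- names(lexicon)
  forms <- forms[order(-nchar(forms), forms)]
  escaped <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", forms)
  pattern <- paste0("(?<![A-Za-z0-9])(?:",
                    paste(escaped, collapse = "|"),
                    ")(?![A-Za-z0-9])")
  structure(list(pattern = pattern, lexicon = lexicon),
            class = "protein_matcher")
}

#' @export
print.protein_matcher <- function(x, ...) {
  cat(sprintf("Protein matcher: %d surface forms, %d proteins\n",
              length(x$lexicon), length(unique(x$lexicon))))
  invisible(x)
}

#' Count protein mentions in one document
#'
#' Counts occurrences of every lexicon surface form in `title + " " +
#' abstract`; matches of a primary name and a synonym of the same protein sum
#' into one `protein_id`. Proteins with zero occurrences are absent from the
#' result.
#'
#' @param title,abstract document text fields.
#' @param matcher a `protein_matcher`.
#' @return Named integer vector: protein_id -> occurrence count (>= 1).
#' @export
count_mentions <- function(title, abstract, matcher) {
  text <- paste(title, abstract)
  m <- gregexpr(matcher$pattern, text, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] == -1) return(stats::setNames(integer(0), character(0)))
  hits <- tolower(regmatches(text, list(m))[[1]])
  ids <- unname(matcher$lexicon[hits])
  tab <- table(ids)
  stats::setNames(as.integer(tab), names(tab))
}

#' Build a per-document mention index over a corpus
#'
#' @param corpus a `document_corpus`.
#' @param matcher a `protein_matcher`.
#' @return A `mention_index`: named list doc_id -> named integer vector of
#'   per-protein counts (documents with no mentions map to an empty vector).
#' @export
index_mentions <- function(corpus, matcher) {
  idx <- lapply(seq_len(nrow(corpus)), function(i) {
    count_mentions(corpus$title[[i]], corpus$abstract[[i]], matcher)
  })
  names(idx) <- corpus$doc_id
  class(idx) <- "mention_index"
  idx
}

#' Aggregate mention counts into a protein-by-category frequency matrix
#'
#' `tf(p, C)` is the total occurrence count of protein `p` over the documents
#' in cell `C`; a document sitting in several cells contributes to each. In
#' `mode = "binary"` each document contributes at most 1 per protein
#' (document-hit counting) instead of its occurrence count.
#'
#' @param cube a `text_cube`.
#' @param index a `mention_index` (documents missing from the index count as
#'   zero mentions).
#' @param proteins character vector of protein ids fixing the row universe.
#' @param mode `"occurrence"` (default) or `"binary"`.
#' @return A `mention_count_matrix`: integer matrix proteins x categories
#'   with attribute `category_totals`.
#' @export
aggregate_counts <- function(cube, index, proteins,
                             mode = c("occurrence", "binary")) {
  mode <- match.arg(mode)
  cats <- names(cube$cells)
  tf <- matrix(0L, nrow = length(proteins), ncol = length(cats),
               dimnames = list(proteins, cats))
  for (C in cats) {
    for (d in cube$cells[[C]]) {
      counts <- index[[d]]
      if (is.null(counts) || length(counts) == 0) next
      if (mode == "binary") counts[] <- 1L
      keep <- names(counts) %in% proteins
      if (any(keep)) {
        tf[names(counts)[keep], C] <- tf[names(counts)[keep], C] +
          as.integer(counts[keep])
      }
    }
  }
  attr(tf, "category_totals") <- colSums(tf)
  class(tf) <- c("mention_count_matrix", class(tf))
  tf
}

#' Export the mention index as an edge list
#' @param index a `mention_index`
#' @return Data frame `doc_id`, `protein_id`, `count` (one row per positive
#'   count, i.e. one Mentions edge).
#' @export
mention_edges <- function(index) {
  rows <- lapply(names(index), function(d) {
    counts <- index[[d]]
    if (length(counts) == 0) return(NULL)
    data.frame(doc_id = d, protein_id = names(counts),
               count = as.integer(counts), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(doc_id = character(0), protein_id = character(0),
                      count = integer(0))
  }
  rownames(out) <- NULL
  out
}
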
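#' Read a document corpus from JSON Lines
#'
#' One record per line with fields `doc_id`, `title`, `abstract`, `mesh_ids`
#' (array of MeSH descriptor ids). Duplicate `doc_id`s keep the first record
#' with a warning; a missing `doc_id` or an unparseable line is an error
#' naming the line number. `mesh_ids` are deduplicated per document.
#'
#' @param path JSON Lines file path.
#' @return A data frame of class `document_corpus`: `doc_id`, `title`,
#'   `abstract`, list-column `mesh_ids`, in file order.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE),
                    error = function(e) {
                      stopf("unparseable corpus line %d: %s", i, conditionMessage(e))
                    })
    if (is.null(rec$doc_id) || !nzchar(as.character(rec$doc_id)[1])) {
      stopf("corpus line %d is missing 'doc_id'", i)
    }
    recs[[i]] <- list(
      doc_id = as.character(rec$doc_id)[1],
      title = as.character(rec$title %||% "")[1],
      abstract = as.character(rec$abstract %||% "")[1],
      mesh_ids = unique(as.character(unlist(rec$mesh_ids)))
    )
  }
  ids <- vapply(recs, `[[`, character(1), "doc_id")
  dup <- duplicated(ids)
  if (any(dup)) {
    warnf("%d duplicate doc_id(s) in corpus; keeping first occurrence(s): %s",
          sum(dup), paste(unique(ids[dup]), collapse = ", "))
    recs <- recs[!dup]
  }
  as_document_corpus(recs)
}

as_document_corpus <- function(recs) {
  df <- data.frame(
    doc_id = vapply(recs, `[[`, character(1), "doc_id"),
    title = vapply(recs, `[[`, character(1), "title"),
    abstract = vapply(recs, `[[`, character(1), "abstract"),
    stringsAsFactors = FALSE
  )
  df$mesh_ids <- lapply(recs, `[[`, "mesh_ids")
  class(df) <- c("document_corpus", "data.frame")
  df
}

#' Write a corpus to JSON Lines
#' @param corpus a `document_corpus`
#' @param path output path
#' @export
write_corpus <- function(corpus, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(corpus))) {
    writeLines(jsonlite::toJSON(list(
      doc_id = corpus$doc_id[[i]],
      title = corpus$title[[i]],
      abstract = corpus$abstract[[i]],
      mesh_ids = as.list(corpus$mesh_ids[[i]])
    ), auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Assign one document to disease categories by its MeSH indexing
#'
#' A document belongs to a category when it carries at least one descriptor
#' from the category's expanded descriptor set. Documents may belong to
#' several categories; MeSH ids outside every expansion are ignored.
#'
#' @param mesh_ids character vector of the document's descriptor ids.
#' @param expanded named list: abbreviation -> descriptor_id set, as from
#'   [expand_categories()].
#' @return Character vector of category abbreviations (possibly empty).
#' @export
assign_to_categories <- function(mesh_ids, expanded) {
  hits <- vapply(expanded, function(ids) any(mesh_ids %in% ids), logical(1))
  names(expanded)[hits]
}

#' Build the CVD text cube with its OS sub-cube
#'
#' Cells map each disease category to the set of documents carrying one of
#' its descriptors; cells overlap when documents are indexed with several
#' categories. Documents indexed with an OS descriptor are additionally
#' flagged per OS phase. The cube universe is restricted to documents in at
#' least one disease cell; purely-OS or unindexed documents are excluded and
#' counted in the `n_excluded` attribute.
#'
#' @param corpus a `document_corpus`.
#' @param expanded named list of per-category descriptor sets.
#' @param os_vocab an `os_vocabulary` (or NULL for no OS sub-cube).
#' @return A `text_cube` list: `cells` (abbrev -> doc_id set), `os_docs`
#'   (phase -> doc_id set), `universe`, `n_excluded`.
#' @export
build_text_cube <- function(corpus, expanded, os_vocab = NULL) {
  cells <- lapply(expanded, function(ids) character(0))
  assigned <- lapply(corpus$mesh_ids, assign_to_categories, expanded = expanded)
  in_cube <- lengths(assigned) > 0
  for (ab in names(expanded)) {
    has <- vapply(assigned, function(a) ab %in% a, logical(1))
    cells[[ab]] <- corpus$doc_id[has & in_cube]
  }
  universe <- corpus$doc_id[in_cube]

  os_docs <- stats::setNames(
    rep(list(character(0)), length(OS_PHASES)), OS_PHASES)
  if (!is.null(os_vocab) && nrow(os_vocab) > 0) {
    for (ph in OS_PHASES) {
      ph_ids <- os_vocab$descriptor_id[os_vocab$phase == ph]
      has <- vapply(corpus$mesh_ids, function(m) any(m %in% ph_ids),
                    logical(1))
      os_docs[[ph]] <- corpus$doc_id[has & in_cube]
    }
  }
  structure(
    list(cells = cells, os_docs = os_docs, universe = universe,
         n_excluded = sum(!in_cube)),
    class = "text_cube")
}

#' @export
print.text_cube <- function(x, ...) {
  cat(sprintf("Text cube: %d documents in %d category cells (%d excluded)\n",
              length(x$universe), length(x$cells), x$n_excluded))
  invisible(x)
}

#' Per-category document counts of a text cube
#'
#' Mirrors the study's corpus statistics table: per category, the number of
#' documents and the number of those also carrying any OS descriptor, plus a
#' deduplicated grand total.
#'
#' @param cube a `text_cube`.
#' @return Data frame `category`, `n_docs`, `n_os_docs`, with attribute
#'   `total_unique_docs`.
#' @export
cube_statistics <- function(cube) {
  os_all <- unique(unlist(cube$os_docs))
  out <- data.frame(
    category = names(cube$cells),
    n_docs = vapply(cube$cells, length, integer(1)),
    n_os_docs = vapply(cube$cells, function(cell) {
      length(intersect(cell, os_all))
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "total_unique_docs") <- length(cube$universe)
  attr(out, "total_os_docs") <- length(os_all)
  out
}
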
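#' Controlled vocabularies: MeSH descriptors, disease categories, OS terms,
#' proteins, pathways
#'
#' The pipeline is driven by four controlled vocabularies. MeSH descriptors
#' carry dot-delimited tree numbers (e.g. `"C14.280.067"`) that encode their
#' position in the NLM hierarchy; a descriptor is a descendant of a root
#' exactly when one of its tree numbers extends the root's tree number at a
#' dot boundary. Cardiovascular-disease (CVD) categories are defined by sets
#' of root tree numbers; oxidative-stress (OS) descriptors carry a phase
#' (IOS initiation, MOS modulation, OOS outcome) and a subcategory; protein
#' entities carry a UniProt-style accession plus a synonym lexicon used by
#' the mention matcher.
#'
#' @name vocabularies
NULL

TREE_NUMBER_RE <- "^[A-Z][0-9]+(\\.[0-9]+)*$"
OS_PHASES <- c("IOS", "MOS", "OOS")

#' Load a MeSH descriptor vocabulary
#'
#' Reads a descriptor table with columns `descriptor_id`, `name`, and
#' `tree_numbers` (pipe-delimited). Rows sharing a `descriptor_id` are merged
#' by unioning their tree numbers; conflicting names for one ID are an error.
#'
#' @param source path to a CSV file, or a data frame with the three columns.
#' @return A data frame of class `mesh_vocabulary` with one row per unique
#'   descriptor: `descriptor_id`, `name`, and a list-column `tree_numbers`.
#' @export
load_mesh_vocabulary <- function(source) {
  df <- read_table_source(source, c("descriptor_id", "name", "tree_numbers"))
  if (nrow(df) == 0) {
    return(new_mesh_vocabulary(data.frame(
      descriptor_id = character(0), name = character(0)
    ), list()))
  }
  trees <- lapply(df$tree_numbers, split_pipes)
  for (i in seq_along(trees)) {
    bad <- trees[[i]][!grepl(TREE_NUMBER_RE, trees[[i]])]
    if (length(bad) > 0) {
      stopf("malformed tree number '%s' in row %d (descriptor '%s')",
            bad[[1]], i, df$descriptor_id[[i]])
    }
  }
  if (any(!nzchar(df$descriptor_id))) {
    stopf("empty descriptor_id in row %d", which(!nzchar(df$descriptor_id))[1])
  }
  ids <- unique(df$descriptor_id)
  merged_trees <- vector("list", length(ids))
  names(merged_trees) <- ids
  name_of <- character(length(ids))
  names(name_of) <- ids
  for (id in ids) {
    rows <- which(df$descriptor_id == id)
    nm <- unique(df$name[rows])
    if (length(nm) > 1) {
      stopf("descriptor '%s' appears with conflicting names: %s",
            id, paste(sQuote(nm), collapse = ", "))
    }
    name_of[[id]] <- nm
    merged_trees[[id]] <- sort(unique(unlist(trees[rows])))
    if (length(merged_trees[[id]]) == 0) {
      stopf("descriptor '%s' has no tree numbers", id)
    }
  }
  new_mesh_vocabulary(
    data.frame(descriptor_id = ids, name = unname(name_of),
               stringsAsFactors = FALSE),
    unname(merged_trees)
  )
}

new_mesh_vocabulary <- function(df, tree_numbers) {
  df$tree_numbers <- tree_numbers
  class(df) <- c("mesh_vocabulary", "data.frame")
  df
}

#' @export
print.mesh_vocabulary <- function(x, ...) {
  cat(sprintf("MeSH vocabulary: %d descriptors, %d tree numbers\n",
              nrow(x), length(unlist(x$tree_numbers))))
  invisible(x)
}

#' Write a MeSH vocabulary back to CSV (round-trip safe)
#' @param vocab a `mesh_vocabulary`
#' @param path output CSV path
#' @export
write_mesh_vocabulary <- function(vocab, path) {
  out <- data.frame(
    descriptor_id = vocab$descriptor_id,
    name = vocab$name,
    tree_numbers = vapply(vocab$tree_numbers, join_pipes, character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

read_table_source <- function(source, required, sep = ",") {
  if (is.character(source) && length(source) == 1) {
    df <- utils::read.table(source, header = TRUE, sep = sep,
                            quote = "\"", comment.char = "",
                            stringsAsFactors = FALSE,
                            colClasses = "character",
                            encoding = "UTF-8")
  } else if (is.data.frame(source)) {
    df <- as.data.frame(source, stringsAsFactors = FALSE)
    for (cc in intersect(required, names(df))) df[[cc]] <- as.character(df[[cc]])
  } else {
    stopf("source must be a file path or a data frame")
  }
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stopf("source is missing required column(s): %s",
          paste(missing, collapse = ", "))
  }
  df
}

#' Default cardiovascular-disease category definitions
#'
#' The eight CVD categories with their MeSH root tree numbers: CM
#' (cardiomyopathies and heart failure), ARR (cardiac arrhythmias), CHD
#' (congenital heart defects), VD (heart valve diseases), IHD (myocardial
#' ischemia), CCS (cardiac conduction system disease), VOO (ventricular
#' outflow obstruction), and OHD (other heart diseases, a union of seven
#' roots).
#'
#' @return A data frame with columns `abbreviation`, `name`, and a
#'   list-column `root_tree_numbers`.
#' @export
cvd_categories <- function() {
  defs <- list(
    CM  = list("Cardiomyopathies and heart failure",
               c("C14.280.238", "C14.280.434")),
    ARR = list("Arrhythmias, cardiac", "C14.280.067"),
    CHD = list("Heart defects, congenital", "C14.280.400"),
    VD  = list("Heart valve diseases", "C14.280.484"),
    IHD = list("Myocardial ischemia", "C14.280.647"),
    CCS = list("Cardiac conduction system disease", "C14.280.123"),
    VOO = list("Ventricular outflow obstruction", "C14.280.955"),
    OHD = list("Other heart diseases",
               c("C14.280.195", "C14.280.282", "C14.280.383", "C14.280.470",
                 "C14.280.945", "C14.280.459", "C14.280.720"))
  )
  out <- data.frame(
    abbreviation = names(defs),
    name = vapply(defs, `[[`, character(1), 1),
    stringsAsFactors = FALSE
  )
  out$root_tree_numbers <- lapply(defs, function(d) unname(d[[2]]))
  rownames(out) <- NULL
  out
}

#' Expand a disease category to its member MeSH descriptors
#'
#' A descriptor belongs to the category when at least one of its tree numbers
#' either equals a root tree number or extends it at a dot boundary
#' (`root` followed by `"."`). This positional test is how MeSH encodes
#' descent, so no parent table is needed.
#'
#' @param category one row of [cvd_categories()] (or any list with
#'   `abbreviation` and `root_tree_numbers`).
#' @param vocab a `mesh_vocabulary`.
#' @return Character vector of member `descriptor_id`s (sorted, unique).
#' @export
expand_category <- function(category, vocab) {
  roots <- unlist(category$root_tree_numbers)
  if (length(roots) == 0) {
    stopf("category '%s' has no root tree numbers",
          category$abbreviation %||% "<unnamed>")
  }
  if (nrow(vocab) == 0) return(character(0))
  hits <- vapply(vocab$tree_numbers, function(trees) {
    any(vapply(roots, function(r) {
      any(trees == r | startsWith(trees, paste0(r, ".")))
    }, logical(1)))
  }, logical(1))
  sort(unique(vocab$descriptor_id[hits]))
}

#' Expand all categories at once
#' @param categories data frame as from [cvd_categories()]
#' @param vocab a `mesh_vocabulary`
#' @return Named list: abbreviation -> character vector of descriptor_ids.
#' @export
expand_categories <- function(categories, vocab) {
  out <- lapply(seq_len(nrow(categories)), function(i) {
    expand_category(categories[i, ], vocab)
  })
  names(out) <- categories$abbreviation
  out
}

#' Load the oxidative-stress descriptor vocabulary
#'
#' Reads columns `descriptor_id`, `name`, `phase`, `subcategory`. Phases must
#' be IOS, MOS, or OOS. A descriptor listed under several subcategories is
#' kept once with its first-seen phase/subcategory and a warning, because the
#' curated OS list cross-files a few descriptors.
#'
#' @param source CSV path or data frame.
#' @return Data frame of class `os_vocabulary` with one row per unique
#'   descriptor and an attribute `phase_counts` (post-deduplication).
#' @export
load_os_vocabulary <- function(source) {
  df <- read_table_source(source, c("descriptor_id", "name", "phase",
                                    "subcategory"))
  bad <- setdiff(unique(df$phase), OS_PHASES)
  if (length(bad) > 0) {
    stopf("unknown OS phase label(s): %s (expected IOS/MOS/OOS)",
          paste(sQuote(bad), collapse = ", "))
  }
  dup <- duplicated(df$descriptor_id)
  if (any(dup)) {
    warnf("%d OS descriptor row(s) cross-listed under multiple subcategories; keeping first occurrence: %s",
          sum(dup), paste(unique(df$descriptor_id[dup]), collapse = ", "))
    df <- df[!dup, , drop = FALSE]
  }
  rownames(df) <- NULL
  attr(df, "phase_counts") <- vapply(
    OS_PHASES, function(p) sum(df$phase == p), integer(1))
  class(df) <- c("os_vocabulary", "data.frame")
  df
}

#' Load the protein entity list
#'
#' Reads columns `protein_id`, `primary_name`, `synonyms` (pipe-delimited).
#' The match lexicon is the union of primary names and synonyms; a surface
#' form claimed by two different proteins is rejected because dictionary
#' matching could not disambiguate it.
#'
#' @param source CSV path or data frame.
#' @return Data frame of class `protein_entities` with columns `protein_id`,
#'   `primary_name` and list-column `synonyms`; attribute `lexicon` maps
#'   lower-cased surface forms to protein ids.
#' @export
load_protein_entities <- function(source) {
  df <- read_table_source(source, c("protein_id", "primary_name", "synonyms"))
  if (anyDuplicated(df$protein_id)) {
    stopf("duplicate protein_id: %s",
          paste(unique(df$protein_id[duplicated(df$protein_id)]),
                collapse = ", "))
  }
  syns <- lapply(df$synonyms, split_pipes)
  # lexicon: lower-cased surface form -> protein_id
  forms <- character(0); owners <- character(0)
  for (i in seq_len(nrow(df))) {
    f <- unique(tolower(c(df$primary_name[[i]], syns[[i]])))
    f <- f[nzchar(f)]
    forms <- c(forms, f)
    owners <- c(owners, rep(df$protein_id[[i]], length(f)))
  }
  if (anyDuplicated(forms)) {
    clash <- forms[duplicated(forms)][1]
    stopf("ambiguous surface form '%s' claimed by proteins: %s",
          clash, paste(owners[forms == clash], collapse = ", "))
  }
  lexicon <- owners
  names(lexicon) <- forms
  df$synonyms <- syns
  rownames(df) <- NULL
  attr(df, "lexicon") <- lexicon
  class(df) <- c("protein_entities", "data.frame")
  df
}

#' Load a pathway membership table
#'
#' Reads a TSV with columns `pathway_id`, `name`, `parent_id` (empty for
#' roots), `member_protein_ids` (pipe-delimited) and `p_value` (enrichment
#' p-value in \[0,1\], consumed by the pathway score). Parent links must be
#' acyclic.
#'
#' @param source TSV path or data frame.
#' @return Data frame of class `pathway_table` with a list-column
#'   `member_protein_ids` and numeric `p_value`.
#' @export
load_pathways <- function(source) {
  df <- read_table_source(
    source, c("pathway_id", "name", "parent_id", "member_protein_ids",
              "p_value"), sep = "\t")
  if (anyDuplicated(df$pathway_id)) stopf("duplicate pathway_id")
  df$p_value <- as.numeric(df$p_value)
  if (any(is.na(df$p_value) | df$p_value < 0 | df$p_value > 1)) {
    stopf("p_value must be in [0, 1]")
  }
  df$member_protein_ids <- lapply(df$member_protein_ids, split_pipes)
  df$parent_id[is.na(df$parent_id)] <- ""
  check_acyclic_parents(df$pathway_id, df$parent_id)
  rownames(df) <- NULL
  class(df) <- c("pathway_table", "data.frame")
  df
}

check_acyclic_parents <- function(ids, parents) {
  parent_of <- stats::setNames(parents, ids)
  for (id in ids) {
    seen <- character(0)
    cur <- id
    while (nzchar(cur) && cur %in% ids) {
      if (cur %in% seen) stopf("cycle in pathway parent links at '%s'", cur)
      seen <- c(seen, cur)
      cur <- parent_of[[cur]]
    }
  }
  invisible(TRUE)
}

#' Paths to the packaged synthetic vocabulary fixtures
#'
#' The package ships small synthetic stand-in vocabularies mirroring the
#' structure of the curated study inputs: 176 CVD MeSH descriptors under the
#' Table-of-categories roots, 75 unique OS descriptors across the IOS/MOS/OOS
#' phases, 128 calcium-regulating protein entities, and a small
#' Reactome-style pathway table. They are synthetic: identifiers and most
#' names are generated, not transcriptions of NLM or UniProt records.
#'
#' @return Named list of file paths: `cvd_mesh`, `os_mesh`, `proteins`,
#'   `pathways`.
#' @export
packaged_vocabulary_paths <- function() {
  ext <- function(f) system.file("extdata", f, package = "caseolapr",
                                 mustWork = TRUE)
  list(
    cvd_mesh = ext("cvd_mesh_synthetic.csv"),
    os_mesh  = ext("os_mesh_synthetic.csv"),
    proteins = ext("proteins_synthetic.csv"),
    pathways = ext("pathways_synthetic.tsv")
  )
}

#' Merge two MeSH vocabularies into one node set
#'
#' Used to assemble the knowledge graph's MeSH node universe (CVD plus OS
#' descriptors). Descriptor ids are deduplicated.
#'
#' @param ... `mesh_vocabulary` objects or plain character vectors of
#'   descriptor ids.
#' @return Character vector of unique descriptor ids.
#' @export
merge_mesh_ids <- function(...) {
  parts <- lapply(list(...), function(v) {
    if (is.data.frame(v)) v$descriptor_id else as.character(v)
  })
  unique(unlist(parts))
}
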
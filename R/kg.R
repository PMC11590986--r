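#' Build the heterogeneous knowledge graph
#'
#' Four node types — document, protein, MeSH descriptor, pathway — and three
#' edge types: `assigns` (document to MeSH), `mentions` (document to protein,
#' with the occurrence count as an attribute), and `contains` (pathway to
#' protein). Document nodes are the cube universe; MeSH nodes are the union
#' of the CVD and OS vocabularies; document MeSH assignments outside that
#' union are dropped (counted in attribute `n_dropped_assigns`); pathway
#' members outside the curated protein list are dropped (counted in
#' `n_dropped_members`). A mention of a protein that is not in the entity
#' list is an error.
#'
#' @param corpus a `document_corpus` (provides per-document MeSH ids).
#' @param cube a `text_cube` built from the corpus.
#' @param index a `mention_index`.
#' @param proteins a `protein_entities` table.
#' @param cvd_vocab a `mesh_vocabulary` of CVD descriptors.
#' @param os_vocab an `os_vocabulary` (may be NULL).
#' @param pathways a `pathway_table` (may be NULL).
#' @return A `knowledge_graph`: list with data frames `nodes` (`id`, `type`,
#'   `name`, `is_os`) and `edges` (`source`, `target`, `type`, `count`).
#' @export
build_knowledge_graph <- function(corpus, cube, index, proteins,
                                  cvd_vocab, os_vocab = NULL,
                                  pathways = NULL) {
  os_ids <- if (is.null(os_vocab)) character(0) else os_vocab$descriptor_id
  mesh_ids <- merge_mesh_ids(cvd_vocab, os_ids)
  mesh_names <- stats::setNames(cvd_vocab$name, cvd_vocab$descriptor_id)
  if (!is.null(os_vocab)) {
    mesh_names[os_vocab$descriptor_id] <- os_vocab$name
  }

  nodes <- rbind(
    data.frame(id = cube$universe, type = "document",
               name = cube$universe, stringsAsFactors = FALSE),
    data.frame(id = proteins$protein_id, type = "protein",
               name = proteins$primary_name, stringsAsFactors = FALSE),
    data.frame(id = mesh_ids, type = "mesh",
               name = unname(mesh_names[mesh_ids]), stringsAsFactors = FALSE),
    if (!is.null(pathways) && nrow(pathways) > 0) {
      data.frame(id = pathways$pathway_id, type = "pathway",
                 name = pathways$name, stringsAsFactors = FALSE)
    }
  )
  nodes$name[is.na(nodes$name)] <- nodes$id[is.na(nodes$name)]
  nodes$is_os <- nodes$type == "mesh" & nodes$id %in% os_ids
  if (anyDuplicated(nodes$id)) {
    stopf("node id collision across types: %s",
          paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  }

  in_universe <- corpus$doc_id %in% cube$universe
  n_dropped <- 0L
  assigns <- do.call(rbind, lapply(which(in_universe), function(i) {
    m <- corpus$mesh_ids[[i]]
    keep <- m %in% mesh_ids
    n_dropped <<- n_dropped + sum(!keep)
    if (!any(keep)) return(NULL)
    data.frame(source = corpus$doc_id[[i]], target = m[keep],
               type = "assigns", count = NA_integer_,
               stringsAsFactors = FALSE)
  }))

  mentions <- do.call(rbind, lapply(cube$universe, function(d) {
    counts <- index[[d]]
    if (is.null(counts) || length(counts) == 0) return(NULL)
    unknown <- setdiff(names(counts), proteins$protein_id)
    if (length(unknown) > 0) {
      stopf("mention of unknown protein id(s): %s",
            paste(unknown, collapse = ", "))
    }
    data.frame(source = d, target = names(counts), type = "mentions",
               count = as.integer(counts), stringsAsFactors = FALSE)
  }))

  n_dropped_members <- 0L
  contains <- if (!is.null(pathways) && nrow(pathways) > 0) {
    do.call(rbind, lapply(seq_len(nrow(pathways)), function(i) {
      mem <- pathways$member_protein_ids[[i]]
      keep <- mem %in% proteins$protein_id
      n_dropped_members <<- n_dropped_members + sum(!keep)
      if (!any(keep)) return(NULL)
      data.frame(source = pathways$pathway_id[[i]], target = mem[keep],
                 type = "contains", count = NA_integer_,
                 stringsAsFactors = FALSE)
    }))
  }

  empty_edges <- data.frame(source = character(0), target = character(0),
                            type = character(0), count = integer(0))
  edges <- rbind(assigns %||% empty_edges, mentions %||% empty_edges,
                 contains %||% empty_edges)
  edges <- edges[!duplicated(edges[c("source", "target", "type")]), ,
                 drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges,
                 n_dropped_assigns = n_dropped,
                 n_dropped_members = n_dropped_members),
            class = "knowledge_graph")
}

#' @export
print.knowledge_graph <- function(x, ...) {
  nt <- table(x$nodes$type)
  et <- table(x$edges$type)
  cat("Knowledge graph\n  nodes:",
      paste(sprintf("%s=%d", names(nt), nt), collapse = ", "),
      "\n  edges:",
      paste(sprintf("%s=%d", names(et), et), collapse = ", "), "\n")
  invisible(x)
}

#' Export a knowledge graph to disk
#'
#' `bulk_csv` writes one `nodes_<type>.csv` per node type with graph-database
#' bulk-import headers (`id:ID`, `:LABEL`, plus attributes) and one
#' `edges_<type>.csv` per edge type (`:START_ID`, `:END_ID`, `:TYPE`,
#' attributes). `graphml` writes a single typed-attribute GraphML file via
#' igraph. Both round-trip through [import_graph()].
#'
#' @param kg a `knowledge_graph`.
#' @param directory output directory (created if needed).
#' @param format `"bulk_csv"` or `"graphml"`.
#' @return Invisibly, the written file paths.
#' @export
export_graph <- function(kg, directory, format = c("bulk_csv", "graphml")) {
  format <- match.arg(format)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (format == "bulk_csv") {
    paths <- character(0)
    for (ty in sort(unique(kg$nodes$type))) {
      sub <- kg$nodes[kg$nodes$type == ty, , drop = FALSE]
      out <- data.frame(sub$id, sub$type, sub$name, sub$is_os)
      names(out) <- c("id:ID", ":LABEL", "name", "is_os")
      p <- file.path(directory, sprintf("nodes_%s.csv", ty))
      utils::write.csv(out, p, row.names = FALSE)
      paths <- c(paths, p)
    }
    for (ty in sort(unique(kg$edges$type))) {
      sub <- kg$edges[kg$edges$type == ty, , drop = FALSE]
      out <- data.frame(sub$source, sub$target, sub$type, sub$count)
      names(out) <- c(":START_ID", ":END_ID", ":TYPE", "count")
      p <- file.path(directory, sprintf("edges_%s.csv", ty))
      utils::write.csv(out, p, row.names = FALSE)
      paths <- c(paths, p)
    }
    return(invisible(paths))
  }
  g <- as_igraph(kg)
  p <- file.path(directory, "kg.graphml")
  igraph::write_graph(g, p, format = "graphml")
  invisible(p)
}

#' Convert a knowledge graph to an igraph object
#' @param kg a `knowledge_graph`
#' @return An undirected-compatible igraph graph with `type`/`name` vertex
#'   attributes and `type`/`count` edge attributes.
#' @export
as_igraph <- function(kg) {
  vertices <- data.frame(name = kg$nodes$id, type = kg$nodes$type,
                         label = kg$nodes$name, is_os = kg$nodes$is_os,
                         stringsAsFactors = FALSE)
  edges <- kg$edges
  edges$count[is.na(edges$count)] <- -1L
  igraph::graph_from_data_frame(
    edges[c("source", "target", "type", "count")],
    directed = FALSE, vertices = vertices)
}

#' Import a knowledge graph written by [export_graph()]
#' @param directory directory holding the exported files.
#' @param format `"bulk_csv"` or `"graphml"`.
#' @return A `knowledge_graph`.
#' @export
import_graph <- function(directory, format = c("bulk_csv", "graphml")) {
  format <- match.arg(format)
  if (format == "bulk_csv") {
    nf <- list.files(directory, "^nodes_.*\\.csv$", full.names = TRUE)
    ef <- list.files(directory, "^edges_.*\\.csv$", full.names = TRUE)
    nodes <- do.call(rbind, lapply(nf, function(p) {
      df <- utils::read.csv(p, check.names = FALSE,
                            colClasses = c("character", "character",
                                           "character", "logical"))
      stats::setNames(df, c("id", "type", "name", "is_os"))
    }))
    edges <- do.call(rbind, lapply(ef, function(p) {
      df <- utils::read.csv(p, check.names = FALSE,
                            colClasses = c("character", "character",
                                           "character", "integer"))
      stats::setNames(df, c("source", "target", "type", "count"))
    }))
    if (is.null(edges)) {
      edges <- data.frame(source = character(0), target = character(0),
                          type = character(0), count = integer(0))
    }
    rownames(nodes) <- rownames(edges) <- NULL
    return(structure(list(nodes = nodes, edges = edges,
                          n_dropped_assigns = NA_integer_,
                          n_dropped_members = NA_integer_),
                     class = "knowledge_graph"))
  }
  g <- igraph::read_graph(file.path(directory, "kg.graphml"),
                          format = "graphml")
  nodes <- data.frame(
    id = igraph::V(g)$name, type = igraph::V(g)$type,
    name = igraph::V(g)$label, is_os = as.logical(igraph::V(g)$is_os),
    stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g)
  count <- as.integer(igraph::E(g)$count)
  count[count < 0] <- NA_integer_
  edges <- data.frame(source = el[, 1], target = el[, 2],
                      type = igraph::E(g)$type, count = count,
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges,
                 n_dropped_assigns = NA_integer_,
                 n_dropped_members = NA_integer_),
            class = "knowledge_graph")
}

#' Protein / OS-descriptor document co-occurrence
#'
#' A protein co-occurs with an OS descriptor when some document both mentions
#' the protein and is assigned the descriptor (graph traversal
#' document–mentions–protein and document–assigns–MeSH). Only pairs with at
#' least one supporting document are returned.
#'
#' @param kg a `knowledge_graph`.
#' @param within_docs optional character vector restricting the supporting
#'   documents (e.g. one category's cube cell); default: all documents.
#' @return Data frame `protein_id`, `os_descriptor_id`, `n_docs`.
#' @export
protein_os_cooccurrence <- function(kg, within_docs = NULL) {
  os_ids <- kg$nodes$id[kg$nodes$type == "mesh" & kg$nodes$is_os]
  men <- kg$edges[kg$edges$type == "mentions", , drop = FALSE]
  asg <- kg$edges[kg$edges$type == "assigns" &
                    kg$edges$target %in% os_ids, , drop = FALSE]
  if (!is.null(within_docs)) {
    men <- men[men$source %in% within_docs, , drop = FALSE]
    asg <- asg[asg$source %in% within_docs, , drop = FALSE]
  }
  if (nrow(men) == 0 || nrow(asg) == 0) {
    return(data.frame(protein_id = character(0),
                      os_descriptor_id = character(0),
                      n_docs = integer(0)))
  }
  joined <- merge(men[c("source", "target")], asg[c("source", "target")],
                  by = "source", suffixes = c("_protein", "_mesh"))
  agg <- stats::aggregate(
    list(n_docs = joined$source),
    by = list(protein_id = joined$target_protein,
              os_descriptor_id = joined$target_mesh),
    FUN = function(x) length(unique(x)))
  agg <- agg[order(agg$protein_id, agg$os_descriptor_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Count proteins linked to both oxidative stress and a disease category
#'
#' Number of proteins that co-occur with at least one OS descriptor and have
#' a positive CaseOLAP score in at least one category.
#'
#' @param cooccurrence table from [protein_os_cooccurrence()].
#' @param scores a `score_matrix`.
#' @return Integer count.
#' @export
count_os_cvd_proteins <- function(cooccurrence, scores) {
  if (nrow(cooccurrence) == 0) return(0L)
  scoring <- scores$proteins[apply(scores$score, 1, max) > 0]
  length(intersect(unique(cooccurrence$protein_id), scoring))
}

#' Score one OS molecule in one disease category
#'
#' The OS molecule score is the arithmetic mean of the CaseOLAP scores, in
#' the given category, of all proteins co-occurring with the molecule. A
#' molecule with no co-occurring protein has no score (`NA`).
#'
#' @param cooccurrence table from [protein_os_cooccurrence()].
#' @param scores a `score_matrix`.
#' @param molecule OS descriptor id.
#' @param category category abbreviation.
#' @return Numeric score, or `NA_real_` if the molecule has no co-occurring
#'   protein.
#' @export
os_molecule_score <- function(cooccurrence, scores, molecule, category) {
  prots <- cooccurrence$protein_id[cooccurrence$os_descriptor_id == molecule]
  prots <- intersect(unique(prots), scores$proteins)
  if (length(prots) == 0) return(NA_real_)
  mean(scores$score[prots, category])
}

#' Score one pathway in one disease category
#'
#' The pathway score averages, over the pathway's member proteins restricted
#' to the curated entity set (reverse mapping), the member's CaseOLAP score
#' in the category damped by the pathway's enrichment significance:
#' `mean(S(p, category) * (1 - p_value))`. A pathway with no member in the
#' entity set has no score (`NA`).
#'
#' @param pathways a `pathway_table`.
#' @param scores a `score_matrix`.
#' @param pathway pathway id.
#' @param category category abbreviation.
#' @return Numeric score, or `NA_real_`.
#' @export
pathway_score <- function(pathways, scores, pathway, category) {
  i <- match(pathway, pathways$pathway_id)
  if (is.na(i)) stopf("unknown pathway '%s'", pathway)
  members <- intersect(pathways$member_protein_ids[[i]], scores$proteins)
  if (length(members) == 0) return(NA_real_)
  mean(scores$score[members, category] * (1 - pathways$p_value[[i]]))
}

#' Association table of OS molecules across all categories
#'
#' One row per (molecule, category) for every molecule with at least one
#' co-occurring protein. `n_support_docs` is the number of distinct documents
#' linking the molecule to any co-occurring protein.
#'
#' @param cooccurrence table from [protein_os_cooccurrence()].
#' @param scores a `score_matrix`.
#' @return Data frame `entity_id`, `category`, `score`, `n_support_docs`
#'   with attribute `entity_kind = "os_molecule"`.
#' @export
score_os_molecules <- function(cooccurrence, scores) {
  mols <- sort(unique(cooccurrence$os_descriptor_id))
  rows <- list()
  for (m in mols) {
    support <- sum(cooccurrence$n_docs[cooccurrence$os_descriptor_id == m])
    for (C in scores$categories) {
      s <- os_molecule_score(cooccurrence, scores, m, C)
      rows[[length(rows) + 1]] <- data.frame(
        entity_id = m, category = C, score = s,
        n_support_docs = support, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows) %||% data.frame(
    entity_id = character(0), category = character(0), score = numeric(0),
    n_support_docs = integer(0))
  attr(out, "entity_kind") <- "os_molecule"
  out
}

#' Association table of pathways across all categories
#'
#' One row per (pathway, category) for every pathway with at least one member
#' in the curated entity set; `n_support_docs` here counts the supporting
#' member proteins.
#'
#' @param pathways a `pathway_table`.
#' @param scores a `score_matrix`.
#' @return Data frame `entity_id`, `category`, `score`, `n_support_docs`
#'   with attribute `entity_kind = "pathway"`.
#' @export
score_pathways <- function(pathways, scores) {
  rows <- list()
  for (i in seq_len(nrow(pathways))) {
    members <- intersect(pathways$member_protein_ids[[i]], scores$proteins)
    if (length(members) == 0) next
    for (C in scores$categories) {
      rows[[length(rows) + 1]] <- data.frame(
        entity_id = pathways$pathway_id[[i]], category = C,
        score = pathway_score(pathways, scores, pathways$pathway_id[[i]], C),
        n_support_docs = length(members), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows) %||% data.frame(
    entity_id = character(0), category = character(0), score = numeric(0),
    n_support_docs = integer(0))
  attr(out, "entity_kind") <- "pathway"
  out
}

#' Document- and protein-level OS-phase by category overlap tables
#'
#' The document matrix counts, per (OS phase, category), documents in the
#' category cell that carry an OS descriptor of the phase. The protein matrix
#' counts proteins with a positive CaseOLAP score in the category that are
#' mentioned by at least one such document.
#'
#' @param cube a `text_cube`.
#' @param index a `mention_index`.
#' @param scores a `score_matrix`.
#' @return List of two integer matrices `documents` and `proteins`
#'   (rows = OS phases, columns = categories).
#' @export
overlap_tables <- function(cube, index, scores) {
  phases <- names(cube$os_docs)
  cats <- names(cube$cells)
  docm <- matrix(0L, length(phases), length(cats),
                 dimnames = list(phases, cats))
  prom <- docm
  for (ph in phases) {
    for (C in cats) {
      shared <- intersect(cube$cells[[C]], cube$os_docs[[ph]])
      docm[ph, C] <- length(shared)
      if (length(shared) > 0) {
        mentioned <- unique(unlist(lapply(shared, function(d) {
          names(index[[d]])
        })))
        mentioned <- intersect(mentioned, scores$proteins)
        prom[ph, C] <- sum(scores$score[mentioned, C] > 0)
      }
    }
  }
  list(documents = docm, proteins = prom)
}
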
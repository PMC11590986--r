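# Shared fixtures and independent oracles, all built in code.

# Four-document worked example used across modules (hand-enumerated):
#   d1 [ARR]            mentions RyR2 x2
#   d2 [ARR, OS/MOS]    mentions RyR2 x1, SERCA2 x1
#   d3 [CM]             mentions SERCA2 x2
#   d4 [CM]             no mentions
micro_fixture <- function() {
  mesh <- load_mesh_vocabulary(data.frame(
    descriptor_id = c("D001", "D002"),
    name = c("Arrhythmias, Cardiac", "Cardiomyopathies"),
    tree_numbers = c("C14.280.067", "C14.280.238")))
  os <- load_os_vocabulary(data.frame(
    descriptor_id = "D100", name = "Glutathione",
    phase = "MOS", subcategory = "redox metabolites"))
  proteins <- load_protein_entities(data.frame(
    protein_id = c("P1", "P2"),
    primary_name = c("RyR2", "SERCA2"),
    synonyms = c("ryanodine receptor 2", "calcium pump 2")))
  cats <- cvd_categories()
  cats <- cats[cats$abbreviation %in% c("ARR", "CM"), ]

  texts <- list(
    d1 = list(mesh = "D001", ab = "RyR2 interacts with RyR2"),
    d2 = list(mesh = c("D001", "D100"), ab = "RyR2 phosphorylates SERCA2"),
    d3 = list(mesh = "D002", ab = "SERCA2 stabilizes SERCA2"),
    d4 = list(mesh = "D002", ab = "no relevant proteins here"))
  path <- tempfile(fileext = ".jsonl")
  con <- file(path, "w")
  for (d in names(texts)) {
    writeLines(jsonlite::toJSON(list(
      doc_id = d, title = "", abstract = texts[[d]]$ab,
      mesh_ids = as.list(texts[[d]]$mesh)), auto_unbox = TRUE), con)
  }
  close(con)
  corpus <- read_corpus(path)

  expanded <- expand_categories(cats, mesh)
  cube <- build_text_cube(corpus, expanded, os)
  matcher <- compile_matcher(proteins)
  index <- index_mentions(corpus, matcher)
  counts <- aggregate_counts(cube, index, proteins$protein_id)
  scores <- compute_score_matrix(counts)
  kg <- build_knowledge_graph(corpus, cube, index, proteins, mesh, os)
  list(mesh = mesh, os = os, proteins = proteins, categories = cats,
       corpus = corpus, expanded = expanded, cube = cube, matcher = matcher,
       index = index, counts = counts, scores = scores, kg = kg,
       corpus_path = path)
}

# random undirected graph as a knowledge_graph with protein/document/mesh
# types; proteins and mesh connect only through documents (schema-faithful)
random_schema_kg <- function(seed, n_prot = 4, n_doc = 12, n_mesh = 5,
                             p_mention = 0.25, p_assign = 0.3) {
  set.seed(seed)
  prot <- sprintf("p%02d", seq_len(n_prot))
  docs <- sprintf("d%02d", seq_len(n_doc))
  mesh <- sprintf("m%02d", seq_len(n_mesh))
  nodes <- data.frame(
    id = c(prot, docs, mesh),
    type = rep(c("protein", "document", "mesh"), c(n_prot, n_doc, n_mesh)),
    name = c(prot, docs, mesh), stringsAsFactors = FALSE)
  nodes$is_os <- nodes$type == "mesh"
  edges <- list()
  for (d in docs) {
    for (p in prot) if (runif(1) < p_mention) {
      edges[[length(edges) + 1]] <- data.frame(
        source = d, target = p, type = "mentions", count = 1L)
    }
    for (m in mesh) if (runif(1) < p_assign) {
      edges[[length(edges) + 1]] <- data.frame(
        source = d, target = m, type = "assigns", count = NA_integer_)
    }
  }
  edges <- do.call(rbind, edges)
  if (is.null(edges)) {
    edges <- data.frame(source = character(0), target = character(0),
                        type = character(0), count = integer(0))
  }
  structure(list(nodes = nodes, edges = edges,
                 n_dropped_assigns = 0L, n_dropped_members = 0L),
            class = "knowledge_graph")
}

# independent brute-force link-prediction oracle over a dense adjacency
# matrix (separate code path from kg_adjacency)
bf_adjacency_matrix <- function(kg) {
  ids <- kg$nodes$id
  A <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_len(nrow(kg$edges))) {
    s <- kg$edges$source[[i]]; t <- kg$edges$target[[i]]
    A[s, t] <- 1L
    A[t, s] <- 1L
  }
  A
}

bf_pair_score <- function(A, a, b, measure) {
  deg <- rowSums(A)
  common <- names(which(A[a, ] == 1 & A[b, ] == 1))
  switch(measure,
    common_neighbors = length(common),
    adamic_adar = {
      d <- deg[common]; sum(1 / log(d[d >= 2]))
    },
    resource_allocation = if (length(common) == 0) 0 else
      sum(1 / deg[common]),
    preferential_attachment = deg[[a]] * deg[[b]])
}

# direct-mean oracles for the association scores
oracle_os_score <- function(cooc, scores, molecule, category) {
  ps <- unique(cooc$protein_id[cooc$os_descriptor_id == molecule])
  vals <- vapply(ps, function(p) scores$score[p, category], numeric(1))
  mean(vals)
}

oracle_pathway_score <- function(members, p_value, scores, category) {
  vals <- vapply(members, function(p) scores$score[p, category], numeric(1))
  mean(vals * (1 - p_value))
}

# minimal score_matrix wrapper for hand-specified score values
manual_scores <- function(score) {
  structure(list(
    proteins = rownames(score), categories = colnames(score),
    popularity = score, distinctiveness = score, score = score,
    n_scoring = sum(apply(score, 1, max) > 0)), class = "score_matrix")
}
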
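#' Topology-based link prediction on the knowledge graph
#'
#' Proteins and MeSH descriptors are never directly adjacent in this schema
#' (they connect only through documents), so every protein x MeSH pair is a
#' candidate link. Candidate pairs are scored with the common-neighbour
#' family of topological measures, treating all edges as undirected:
#'
#' * `common_neighbors`: `|N(a) intersect N(b)|`
#' * `adamic_adar`: `sum over common w with deg(w) >= 2 of 1 / ln(deg(w))`
#' * `resource_allocation`: `sum over common w of 1 / deg(w)`
#' * `preferential_attachment`: `|N(a)| * |N(b)|`
#'
#' A higher score suggests a higher likelihood of an undiscovered
#' relationship between the pair.
#'
#' @name link_prediction
NULL

LINKPRED_MEASURES <- c("common_neighbors", "adamic_adar",
                       "resource_allocation", "preferential_attachment")

# adjacency list over all edge types, undirected, named by node id
kg_adjacency <- function(kg) {
  ids <- kg$nodes$id
  adj <- stats::setNames(rep(list(character(0)), length(ids)), ids)
  if (nrow(kg$edges) > 0) {
    by_src <- split(kg$edges$target, kg$edges$source)
    by_tgt <- split(kg$edges$source, kg$edges$target)
    for (nm in names(by_src)) adj[[nm]] <- c(adj[[nm]], by_src[[nm]])
    for (nm in names(by_tgt)) adj[[nm]] <- c(adj[[nm]], by_tgt[[nm]])
    adj <- lapply(adj, unique)
  }
  adj
}

#' Neighbours of a node across all edge types
#'
#' @param kg a `knowledge_graph`.
#' @param node_id node id.
#' @return Character vector of adjacent node ids (undirected).
#' @export
kg_neighbors <- function(kg, node_id) {
  if (!node_id %in% kg$nodes$id) stopf("unknown node '%s'", node_id)
  e <- kg$edges
  unique(c(e$target[e$source == node_id], e$source[e$target == node_id]))
}

#' Topological link-prediction score for one node pair
#'
#' @param kg a `knowledge_graph`.
#' @param a,b node ids, `a != b`.
#' @param measure one of `"common_neighbors"`, `"adamic_adar"`,
#'   `"resource_allocation"`, `"preferential_attachment"`.
#' @return Non-negative numeric score, symmetric in `(a, b)`.
#' @export
pair_score <- function(kg, a, b,
                       measure = c("adamic_adar", "common_neighbors",
                                   "resource_allocation",
                                   "preferential_attachment")) {
  measure <- match.arg(measure)
  if (a == b) stopf("pair_score requires two distinct nodes")
  adj <- kg_adjacency(kg)
  pair_score_adj(adj, a, b, measure)
}

pair_score_adj <- function(adj, a, b, measure) {
  na <- adj[[a]]; nb <- adj[[b]]
  if (is.null(na) || is.null(nb)) stopf("unknown node in pair (%s, %s)", a, b)
  if (measure == "preferential_attachment") {
    return(length(na) * length(nb))
  }
  common <- intersect(na, nb)
  if (length(common) == 0) return(0)
  switch(measure,
    common_neighbors = length(common),
    adamic_adar = {
      deg <- lengths(adj[common])
      sum(1 / log(deg[deg >= 2]))
    },
    resource_allocation = sum(1 / lengths(adj[common]))
  )
}

#' Rank all candidate node pairs of two types
#'
#' Scores the full type-a x type-b product (the schema guarantees no direct
#' protein-MeSH edges; any existing direct edge is an error), sorts by score
#' descending with ties broken lexicographically by `(node_a, node_b)`.
#'
#' @param kg a `knowledge_graph`.
#' @param type_a,type_b node types, e.g. `"protein"` and `"mesh"`.
#' @param measure scoring measure, see [pair_score()].
#' @param b_subset optional character vector restricting the type-b nodes
#'   (e.g. only OS descriptors, or only CVD descriptors).
#' @return Data frame `node_a`, `node_b`, `measure`, `score` over every
#'   candidate pair (zeros included), sorted.
#' @export
rank_candidate_pairs <- function(kg, type_a, type_b,
                                 measure = c("adamic_adar",
                                             "common_neighbors",
                                             "resource_allocation",
                                             "preferential_attachment"),
                                 b_subset = NULL) {
  measure <- match.arg(measure)
  as_ <- sort(kg$nodes$id[kg$nodes$type == type_a])
  bs <- sort(kg$nodes$id[kg$nodes$type == type_b])
  if (!is.null(b_subset)) bs <- intersect(bs, b_subset)
  e <- kg$edges
  direct <- (e$source %in% as_ & e$target %in% bs) |
    (e$source %in% bs & e$target %in% as_)
  if (any(direct)) {
    stopf("candidate universe violated: %d direct %s-%s edge(s) exist",
          sum(direct), type_a, type_b)
  }
  adj <- kg_adjacency(kg)
  grid <- expand.grid(node_a = as_, node_b = bs, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid$measure <- measure
  grid$score <- vapply(seq_len(nrow(grid)), function(i) {
    pair_score_adj(adj, grid$node_a[[i]], grid$node_b[[i]], measure)
  }, numeric(1))
  grid <- grid[order(-grid$score, grid$node_a, grid$node_b), , drop = FALSE]
  rownames(grid) <- NULL
  grid
}

#' Reshape a ranked pair table into a heatmap-ready wide matrix
#'
#' @param pairs table from [rank_candidate_pairs()].
#' @return Numeric matrix, rows = `node_a` ids, columns = `node_b` ids.
#' @export
pair_score_matrix <- function(pairs) {
  as_ <- sort(unique(pairs$node_a))
  bs <- sort(unique(pairs$node_b))
  m <- matrix(0, length(as_), length(bs), dimnames = list(as_, bs))
  m[cbind(pairs$node_a, pairs$node_b)] <- pairs$score
  m
}
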
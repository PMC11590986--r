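#' Hierarchical sunburst aggregation
#'
#' Aggregates an association table over a hierarchy for sunburst-style
#' display: each scored entity is a leaf whose value is the sum of its scores
#' over the categories of interest (e.g. the ARR + CCS cluster); every
#' internal node's value is the sum of its children's values, so the root
#' value equals the total over all leaves.
#'
#' @param scored_items association table (`entity_id`, `category`, `score`,
#'   `n_support_docs`) as from [score_os_molecules()] or [score_pathways()].
#' @param hierarchy data frame `node_id`, `parent_id` (empty/NA for the
#'   root), `name`; must be acyclic with a single root.
#' @param categories_of_interest character vector of category abbreviations
#'   summed into leaf values.
#' @return Nested list with fields `name`, `value`, `children` (absent for
#'   leaves), ready for [jsonlite::toJSON()].
#' @export
sunburst_export <- function(scored_items, hierarchy, categories_of_interest) {
  hierarchy$parent_id[is.na(hierarchy$parent_id)] <- ""
  check_acyclic_parents(hierarchy$node_id, hierarchy$parent_id)
  unknown <- setdiff(unique(scored_items$entity_id), hierarchy$node_id)
  if (length(unknown) > 0) {
    stopf("scored item(s) not present in the hierarchy: %s",
          paste(unknown, collapse = ", "))
  }
  keep <- scored_items$category %in% categories_of_interest &
    !is.na(scored_items$score)
  leaf_value <- tapply(scored_items$score[keep],
                       scored_items$entity_id[keep], sum)

  roots <- hierarchy$node_id[!nzchar(hierarchy$parent_id) |
                               !(hierarchy$parent_id %in% hierarchy$node_id)]
  if (length(roots) != 1) {
    stopf("hierarchy must have exactly one root (found %d)", length(roots))
  }
  children_of <- split(hierarchy$node_id, hierarchy$parent_id)
  name_of <- stats::setNames(hierarchy$name, hierarchy$node_id)

  build <- function(id) {
    kids <- children_of[[id]]
    own <- if (id %in% names(leaf_value)) unname(leaf_value[[id]]) else 0
    node <- list(name = unname(name_of[[id]]), value = own)
    if (length(kids) > 0) {
      node$children <- lapply(sort(kids), build)
      node$value <- own +
        sum(vapply(node$children, `[[`, numeric(1), "value"))
    }
    node
  }
  build(roots)
}

#' Write a sunburst tree to a JSON file
#' @param tree nested list from [sunburst_export()]
#' @param path output path
#' @export
write_sunburst_json <- function(tree, path) {
  jsonlite::write_json(tree, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Sum of all leaf values in a sunburst tree
#'
#' Convenience check of value conservation: for a tree whose internal nodes
#' carry no own score, this equals the root value.
#'
#' @param tree nested list from [sunburst_export()]
#' @return Numeric sum over leaves.
#' @export
sunburst_leaf_sum <- function(tree) {
  if (is.null(tree$children)) return(tree$value)
  sum(vapply(tree$children, sunburst_leaf_sum, numeric(1)))
}
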
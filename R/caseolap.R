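#' CaseOLAP scoring
#'
#' CaseOLAP quantifies how relevant an entity (here a protein) is to a
#' category of documents (here a disease category) by combining two bounded
#' components:
#'
#' * **popularity** — how strongly the protein is represented inside the
#'   category: a log-saturated frequency normalised by the category's total
#'   mention mass, `Pop(p,C) = ln(1 + tf(p,C)) / ln(1 + total(C))`;
#' * **distinctiveness** — how concentrated the protein's relative frequency
#'   is in this category versus the alternatives:
#'   `Dist(p,C) = rtf(p,C) / sum_C' rtf(p,C')` with
#'   `rtf(p,C) = tf(p,C) / total(C)`.
#'
#' The combined score is `S = Pop * Dist`, elementwise, bounded in \[0,1\],
#' and zero exactly where `tf` is zero. Because `rtf` is scale-free in the
#' per-category totals, distinctiveness is invariant to replicating all of
#' one category's documents, which is what makes the score robust to class
#' imbalance between disease categories.
#'
#' @name caseolap
NULL

#' Popularity of a protein inside one category
#'
#' @param tf_pC occurrence count of the protein in the category.
#' @param total_C total occurrence count over all proteins in the category.
#' @param denominator `"total"` (default) normalises by the category total;
#'   `"max"` by the largest per-protein count in the category (pass it as
#'   `total_C`).
#' @return `ln(1 + tf) / ln(1 + total)` in \[0,1\]; 0 when the category is
#'   empty.
#' @export
popularity <- function(tf_pC, total_C, denominator = c("total", "max")) {
  match.arg(denominator)  # both use the same saturation; caller picks total_C
  if (any(tf_pC > total_C)) {
    stopf("tf exceeds its category denominator (tf=%s > %s)",
          max(tf_pC), min(total_C[tf_pC > total_C]))
  }
  out <- ifelse(total_C > 0, log1p(tf_pC) / log1p(total_C), 0)
  as.numeric(out)
}

#' Distinctiveness of one protein across categories
#'
#' @param tf_p named numeric vector: per-category counts for one protein.
#' @param category_totals named numeric vector of per-category totals
#'   (same names).
#' @return Named numeric vector of distinctiveness values summing to 1 for
#'   any mentioned protein; identically 0 for an unmentioned one.
#' @export
distinctiveness <- function(tf_p, category_totals) {
  stopifnot(identical(names(tf_p), names(category_totals)))
  rtf <- ifelse(category_totals > 0, tf_p / category_totals, 0)
  s <- sum(rtf)
  if (s == 0) return(stats::setNames(rep(0, length(tf_p)), names(tf_p)))
  rtf / s
}

#' Compute the full CaseOLAP score matrix
#'
#' @param counts a `mention_count_matrix` from [aggregate_counts()] (or any
#'   named numeric matrix proteins x categories).
#' @param popularity_denominator `"total"` (default) or `"max"`: normalise
#'   popularity by the category's total mention mass or by its maximum
#'   per-protein count.
#' @return A `score_matrix` list: `proteins`, `categories`, and matrices
#'   `popularity`, `distinctiveness`, `score`, plus `n_scoring` (number of
#'   proteins with a positive score in at least one category).
#' @export
compute_score_matrix <- function(counts,
                                 popularity_denominator = c("total", "max")) {
  popularity_denominator <- match.arg(popularity_denominator)
  tf <- unclass(counts)
  attr(tf, "category_totals") <- NULL
  storage.mode(tf) <- "double"
  totals <- colSums(tf)
  denom <- if (popularity_denominator == "total") totals else
    apply(tf, 2, max)

  pop <- tf
  for (C in seq_len(ncol(tf))) {
    pop[, C] <- popularity(tf[, C], rep(denom[[C]], nrow(tf)))
  }
  dist <- tf
  for (p in seq_len(nrow(tf))) {
    dist[p, ] <- distinctiveness(
      stats::setNames(tf[p, ], colnames(tf)),
      stats::setNames(totals, colnames(tf)))
  }
  score <- pop * dist
  structure(list(
    proteins = rownames(tf),
    categories = colnames(tf),
    popularity = pop,
    distinctiveness = dist,
    score = score,
    n_scoring = sum(apply(score, 1, max) > 0)
  ), class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("CaseOLAP score matrix: %d proteins x %d categories (%d scoring)\n",
              length(x$proteins), length(x$categories), x$n_scoring))
  invisible(x)
}

#' Rank proteins within one category by combined score
#'
#' Ties are broken lexicographically by protein id.
#'
#' @param scores a `score_matrix`.
#' @param category category abbreviation.
#' @return Data frame `protein_id`, `score`, sorted.
#' @export
rank_proteins <- function(scores, category) {
  if (!category %in% scores$categories) {
    stopf("unknown category '%s'", category)
  }
  s <- scores$score[, category]
  ord <- order(-s, scores$proteins)
  data.frame(protein_id = scores$proteins[ord], score = unname(s[ord]),
             stringsAsFactors = FALSE)
}

#' Write a score matrix to CSV files
#'
#' Writes three CSVs (`score.csv`, `popularity.csv`, `distinctiveness.csv`),
#' each `protein_id` plus one column per category.
#'
#' @param scores a `score_matrix`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_score_matrix <- function(scores, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("score", "popularity", "distinctiveness")) {
    df <- data.frame(protein_id = scores$proteins, scores[[nm]],
                     check.names = FALSE)
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
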
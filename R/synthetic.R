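#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the statistical structure the analysis assumes: a
#' MeSH-indexed abstract corpus with eight overlapping disease categories of
#' unequal size, OS descriptor co-assignment per phase, and per-document
#' protein mention counts that the dictionary matcher must rediscover from
#' the realized abstract text. Ground truth is a planted set of
#' (protein, category) enrichments.
#'
#' Two designs are available. `"per_category"` plants
#' `planted_pairs_per_category` proteins per category (disjoint across
#' categories when the protein list allows) at Poisson mention rate
#' `lambda_signal` per document, all others at `lambda_background`.
#' `"two_block"` builds the score-profile structure seen in real protein
#' literature: every modelled protein carries a lognormal overall literature
#' popularity `w_p` (heavy-tailed, `sdlog = intensity_sdlog`), one block of
#' proteins is additionally enriched in two focus categories and the other
#' block in the remaining categories, with per-document rate
#' `w_p * (block_base + block_extra * enriched)`.
#'
#' @param n_categories number of disease categories; 8 (the default) uses
#'   the standard CVD abbreviations and root tree numbers.
#' @param n_proteins number of protein entities.
#' @param n_os_descriptors named integer vector, OS descriptors per phase.
#' @param n_mesh_descendants_per_root synthetic descendant descriptors under
#'   each category root.
#' @param docs_per_category documents per category: a single number, or a
#'   vector (named or positional). The default mirrors the document
#'   imbalance of the real corpus (largest category about 11x the smallest).
#' @param planted_pairs_per_category planted proteins per category.
#' @param lambda_signal,lambda_background Poisson mention rates per document
#'   for planted and background pairs (`per_category` design).
#' @param p_os_assign named per-phase probability that a document carries an
#'   OS descriptor of that phase.
#' @param p_multi_category probability a document also carries a second
#'   category's descriptor.
#' @param n_pathways,pathway_size_range pathway table shape.
#' @param p_value_shape `shape1`, `shape2` of the Beta distribution for
#'   pathway p-values (default skewed toward small, enrichment-like values).
#' @param design `"per_category"` or `"two_block"`.
#' @param block_categories the two focus categories of the two-block design.
#' @param n_block1,n_block2 block sizes (two-block design).
#' @param block_base,block_extra,intensity_sdlog two-block rate parameters.
#' @param seed integer seed; every generator draw derives from it.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(n_categories = 8,
                         n_proteins = 128,
                         n_os_descriptors = c(IOS = 12, MOS = 57, OOS = 6),
                         n_mesh_descendants_per_root = 2,
                         docs_per_category = c(CM = 247, ARR = 239,
                                               CHD = 155, VD = 137,
                                               IHD = 473, CCS = 101,
                                               VOO = 43, OHD = 215),
                         planted_pairs_per_category = 10,
                         lambda_signal = 2.0,
                         lambda_background = 0.05,
                         p_os_assign = c(IOS = 0.03, MOS = 0.10, OOS = 0.02),
                         p_multi_category = 0.1,
                         n_pathways = 20,
                         pathway_size_range = c(3, 15),
                         p_value_shape = c(0.5, 9),
                         design = c("per_category", "two_block"),
                         block_categories = c("ARR", "CCS"),
                         n_block1 = 15, n_block2 = 45,
                         block_base = 1.0, block_extra = 0.5,
                         intensity_sdlog = 1.5,
                         seed = 1L) {
  design <- match.arg(design)
  # accept list-valued fields (e.g. restored from YAML) transparently
  n_os_descriptors <- unlist(n_os_descriptors)
  storage.mode(n_os_descriptors) <- "integer"
  p_os_assign <- unlist(p_os_assign)
  docs_per_category <- unlist(docs_per_category)
  pathway_size_range <- as.integer(unlist(pathway_size_range))
  p_value_shape <- as.numeric(unlist(p_value_shape))
  block_categories <- as.character(unlist(block_categories))
  if (lambda_signal <= lambda_background || lambda_background < 0) {
    stopf("need lambda_signal > lambda_background >= 0")
  }
  stopifnot(all(p_os_assign >= 0 & p_os_assign <= 1),
            p_multi_category >= 0, p_multi_category <= 1)
  if (length(docs_per_category) == 1) {
    docs_per_category <- rep(docs_per_category, n_categories)
  }
  if (length(docs_per_category) != n_categories) {
    stopf("docs_per_category must have length 1 or n_categories")
  }
  if (any(docs_per_category <= 0)) stopf("docs_per_category must be positive")
  cfg <- list(
    n_categories = as.integer(n_categories),
    n_proteins = as.integer(n_proteins),
    n_os_descriptors = n_os_descriptors,
    n_mesh_descendants_per_root = as.integer(n_mesh_descendants_per_root),
    docs_per_category = as.integer(docs_per_category),
    planted_pairs_per_category = as.integer(planted_pairs_per_category),
    lambda_signal = lambda_signal,
    lambda_background = lambda_background,
    p_os_assign = p_os_assign,
    p_multi_category = p_multi_category,
    n_pathways = as.integer(n_pathways),
    pathway_size_range = as.integer(pathway_size_range),
    p_value_shape = p_value_shape,
    design = design,
    block_categories = block_categories,
    n_block1 = as.integer(n_block1),
    n_block2 = as.integer(n_block2),
    block_base = block_base,
    block_extra = block_extra,
    intensity_sdlog = intensity_sdlog,
    seed = as.integer(seed)
  )
  class(cfg) <- "synth_config"
  cfg
}

#' Serialize / restore a generator configuration as YAML
#' @param config a `synth_config`
#' @param path YAML file path
#' @export
write_synth_config <- function(config, path) {
  # named vectors become YAML maps (as lists) so names survive the round trip
  serializable <- lapply(unclass(config), function(x) {
    if (!is.null(names(x))) as.list(x) else x
  })
  yaml::write_yaml(serializable, path)
  invisible(path)
}

#' @rdname write_synth_config
#' @export
read_synth_config <- function(path) {
  do.call(synth_config, yaml::read_yaml(path))
}

#' Generate the synthetic vocabularies
#'
#' Produces a MeSH vocabulary (each category root descriptor plus synthetic
#' descendants), the category definitions, an OS vocabulary partitioned into
#' phases, and a collision-free protein entity list. Fully deterministic for
#' a given configuration.
#'
#' @param config a `synth_config`.
#' @return List: `mesh` (`mesh_vocabulary`), `categories` (definitions),
#'   `os` (`os_vocabulary`), `proteins` (`protein_entities`).
#' @export
generate_vocabulary <- function(config) {
  if (config$n_categories == 8) {
    cats <- cvd_categories()
  } else {
    cats <- data.frame(
      abbreviation = sprintf("CAT%d", seq_len(config$n_categories)),
      name = sprintf("Synthetic disease category %d",
                     seq_len(config$n_categories)),
      stringsAsFactors = FALSE)
    cats$root_tree_numbers <- lapply(seq_len(config$n_categories),
                                     function(i) sprintf("C%02d.100", 50 + i))
  }

  rows <- list()
  did <- 0L
  for (i in seq_len(nrow(cats))) {
    for (r in cats$root_tree_numbers[[i]]) {
      did <- did + 1L
      rows[[length(rows) + 1]] <- data.frame(
        descriptor_id = sprintf("DS%05d", did),
        name = sprintf("synthetic %s root descriptor %s",
                       cats$abbreviation[[i]], r),
        tree_numbers = r, stringsAsFactors = FALSE)
      for (j in seq_len(config$n_mesh_descendants_per_root)) {
        did <- did + 1L
        rows[[length(rows) + 1]] <- data.frame(
          descriptor_id = sprintf("DS%05d", did),
          name = sprintf("synthetic %s descendant descriptor %s.%03d",
                         cats$abbreviation[[i]], r, j * 100L),
          tree_numbers = sprintf("%s.%03d", r, j * 100L),
          stringsAsFactors = FALSE)
      }
    }
  }
  mesh <- load_mesh_vocabulary(do.call(rbind, rows))

  subcats <- list(
    IOS = c("reactive oxygen species", "reactive nitrogen species",
            "reactive aldehydes"),
    MOS = c("redox metabolites", "antioxidants", "antioxidant enzymes",
            "redox regulating proteins"),
    OOS = c("protein oxidation", "lipid peroxidation products",
            "oxidative DNA damage", "nitrative DNA damage"))
  os_rows <- list()
  oid <- 0L
  for (ph in names(config$n_os_descriptors)) {
    n <- config$n_os_descriptors[[ph]]
    for (j in seq_len(n)) {
      oid <- oid + 1L
      os_rows[[length(os_rows) + 1]] <- data.frame(
        descriptor_id = sprintf("DO%04d", oid),
        name = sprintf("synthetic OS molecule %d (%s)", oid, ph),
        phase = ph,
        subcategory = subcats[[ph]][((j - 1) %% length(subcats[[ph]])) + 1],
        stringsAsFactors = FALSE)
    }
  }
  os <- load_os_vocabulary(do.call(rbind, os_rows))

  ids <- sprintf("P8%04d", seq_len(config$n_proteins))
  proteins <- load_protein_entities(data.frame(
    protein_id = ids,
    primary_name = sprintf("CAPR%d", seq_len(config$n_proteins)),
    synonyms = sprintf("calcium regulator protein %d",
                       seq_len(config$n_proteins)),
    stringsAsFactors = FALSE))

  list(mesh = mesh, categories = cats, os = os, proteins = proteins)
}

# per-(protein, category) Poisson rate matrix + planted ground truth
make_design <- function(config, protein_ids, category_abbrevs) {
  nP <- length(protein_ids)
  nC <- length(category_abbrevs)
  lambda <- matrix(config$lambda_background, nP, nC,
                   dimnames = list(protein_ids, category_abbrevs))
  perm <- sample(protein_ids)
  if (config$design == "per_category") {
    k <- config$planted_pairs_per_category
    if (k > nP) stopf("planted_pairs_per_category exceeds n_proteins")
    planted <- do.call(rbind, lapply(seq_len(nC), function(ci) {
      idx <- (((ci - 1) * k) %% nP) + seq_len(k)
      idx <- ((idx - 1) %% nP) + 1
      data.frame(protein_id = perm[idx], category = category_abbrevs[[ci]],
                 stringsAsFactors = FALSE)
    }))
    lambda[cbind(planted$protein_id, planted$category)] <- config$lambda_signal
  } else {
    if (config$n_block1 + config$n_block2 > nP) {
      stopf("n_block1 + n_block2 exceeds n_proteins")
    }
    focus <- intersect(config$block_categories, category_abbrevs)
    if (length(focus) < 1) stopf("block_categories not found among categories")
    rest <- setdiff(category_abbrevs, focus)
    b1 <- perm[seq_len(config$n_block1)]
    b2 <- perm[config$n_block1 + seq_len(config$n_block2)]
    w <- stats::setNames(
      exp(stats::rnorm(config$n_block1 + config$n_block2,
                       0, config$intensity_sdlog)), c(b1, b2))
    for (p in c(b1, b2)) {
      enriched <- if (p %in% b1) focus else rest
      lambda[p, ] <- w[[p]] * config$block_base
      lambda[p, enriched] <- w[[p]] * (config$block_base + config$block_extra)
    }
    planted <- rbind(
      expand.grid(protein_id = b1, category = focus,
                  stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE),
      expand.grid(protein_id = b2, category = rest,
                  stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE))
  }
  rownames(planted) <- NULL
  list(lambda = lambda, planted = planted)
}

#' Generate a synthetic corpus with planted ground truth
#'
#' For each category and each of its documents: one of the category's
#' descriptors is assigned; with probability `p_multi_category` a second
#' category contributes a descriptor; each OS phase contributes a descriptor
#' with its `p_os_assign` probability. Protein mention counts are drawn from
#' the design's Poisson rates and realized as repeated surface forms
#' (primary names and synonyms) shuffled into the abstract together with
#' filler tokens, so the matcher has to rediscover them. Planted OS links
#' record every (planted protein, OS descriptor) pair sharing a document.
#'
#' @param config a `synth_config`.
#' @param vocab output of [generate_vocabulary()].
#' @return List: `corpus` (a `document_corpus`), `truth` (list `planted`,
#'   `planted_os_links`), `lambda` (the rate matrix used).
#' @export
generate_corpus <- function(config, vocab) {
  set.seed(config$seed)
  cats <- vocab$categories$abbreviation
  expanded <- expand_categories(vocab$categories, vocab$mesh)
  design <- make_design(config, vocab$proteins$protein_id, cats)

  os_by_phase <- split(vocab$os$descriptor_id, vocab$os$phase)
  phases <- intersect(names(config$p_os_assign), names(os_by_phase))
  filler <- c("cardiac", "myocyte", "signaling", "study", "analysis",
              "function", "expression", "clinical", "model", "pathway")

  recs <- list()
  links <- list()
  doc_no <- 0L
  syn_of <- stats::setNames(
    vapply(vocab$proteins$synonyms, `[[`, character(1), 1),
    vocab$proteins$protein_id)
  name_of <- stats::setNames(vocab$proteins$primary_name,
                             vocab$proteins$protein_id)

  for (ci in seq_along(cats)) {
    C <- cats[[ci]]
    for (j in seq_len(config$docs_per_category[[ci]])) {
      doc_no <- doc_no + 1L
      doc_id <- sprintf("SD%06d", doc_no)
      mesh <- sample(expanded[[C]], 1)
      if (length(cats) > 1 &&
          stats::runif(1) < config$p_multi_category) {
        other <- sample(setdiff(cats, C), 1)
        mesh <- c(mesh, sample(expanded[[other]], 1))
      }
      os_here <- character(0)
      for (ph in phases) {
        if (stats::runif(1) < config$p_os_assign[[ph]]) {
          os_here <- c(os_here, sample(os_by_phase[[ph]], 1))
        }
      }
      counts <- stats::rpois(nrow(design$lambda), design$lambda[, C])
      names(counts) <- rownames(design$lambda)
      mentioned <- counts[counts > 0]
      tokens <- character(0)
      for (p in names(mentioned)) {
        use_primary <- stats::runif(mentioned[[p]]) < 0.5
        tokens <- c(tokens,
                    ifelse(use_primary, name_of[[p]], syn_of[[p]]))
      }
      tokens <- c(tokens, sample(filler, 5 + stats::rpois(1, 3),
                                 replace = TRUE))
      abstract <- paste(sample(tokens), collapse = ". ")
      recs[[doc_no]] <- list(
        doc_id = doc_id,
        title = sprintf("Synthetic record %s on %s", doc_id, C),
        abstract = abstract,
        mesh_ids = unique(c(mesh, os_here))
      )
      if (length(os_here) > 0) {
        planted_here <- design$planted$protein_id[
          design$planted$category == C]
        hit <- intersect(names(mentioned), planted_here)
        if (length(hit) > 0) {
          links[[length(links) + 1]] <- expand.grid(
            protein_id = hit, os_descriptor_id = os_here,
            stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
        }
      }
    }
  }
  planted_os_links <- unique(do.call(rbind, links) %||% data.frame(
    protein_id = character(0), os_descriptor_id = character(0)))
  rownames(planted_os_links) <- NULL
  list(corpus = as_document_corpus(recs),
       truth = list(planted = design$planted,
                    planted_os_links = planted_os_links),
       lambda = design$lambda)
}

#' Draw a mention-count matrix directly from the generative model
#'
#' Fast path for repeated-simulation studies: `tf(p, C)` is drawn
#' `Poisson(n_docs(C) * lambda(p, C))`, the distribution that text
#' realization plus matching plus aggregation induces, without materializing
#' documents.
#'
#' @param config a `synth_config`.
#' @return List: `counts` (`mention_count_matrix`), `truth` (planted pairs),
#'   `lambda`.
#' @export
generate_count_matrix <- function(config) {
  set.seed(config$seed)
  cats <- if (config$n_categories == 8) cvd_categories()$abbreviation else
    sprintf("CAT%d", seq_len(config$n_categories))
  ids <- sprintf("P8%04d", seq_len(config$n_proteins))
  design <- make_design(config, ids, cats)
  ndocs <- rep(config$docs_per_category, length.out = length(cats))
  tf <- design$lambda
  for (ci in seq_along(cats)) {
    tf[, ci] <- stats::rpois(nrow(tf), ndocs[[ci]] * design$lambda[, ci])
  }
  storage.mode(tf) <- "integer"
  attr(tf, "category_totals") <- colSums(tf)
  class(tf) <- c("mention_count_matrix", class(tf))
  list(counts = tf, truth = list(planted = design$planted),
       lambda = design$lambda)
}

#' Generate a synthetic pathway table
#'
#' A three-level Reactome-style hierarchy (one root, a few branches, leaf
#' pathways) with member proteins sampled from the entity list and Beta
#' distributed enrichment p-values.
#'
#' @param config a `synth_config`.
#' @param proteins a `protein_entities` table.
#' @return A `pathway_table`.
#' @export
generate_pathways <- function(config, proteins) {
  set.seed(config$seed + 104729L)  # distinct stream from the corpus draws
  n <- config$n_pathways
  n_branches <- max(2L, min(5L, n %/% 5L))
  rows <- list(data.frame(
    pathway_id = "SYNPW_ROOT", name = "synthetic pathway root",
    parent_id = "", member_protein_ids = "", p_value = "1",
    stringsAsFactors = FALSE))
  for (b in seq_len(n_branches)) {
    rows[[length(rows) + 1]] <- data.frame(
      pathway_id = sprintf("SYNPW_B%02d", b),
      name = sprintf("synthetic pathway branch %d", b),
      parent_id = "SYNPW_ROOT", member_protein_ids = "", p_value = "1",
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    size <- sample(seq(config$pathway_size_range[1],
                       config$pathway_size_range[2]), 1)
    size <- min(size, nrow(proteins))
    members <- sample(proteins$protein_id, size)
    rows[[length(rows) + 1]] <- data.frame(
      pathway_id = sprintf("SYNPW%03d", i),
      name = sprintf("synthetic pathway %d", i),
      parent_id = sprintf("SYNPW_B%02d", ((i - 1) %% n_branches) + 1),
      member_protein_ids = join_pipes(members),
      p_value = format(stats::rbeta(1, config$p_value_shape[1],
                                    config$p_value_shape[2]),
                       digits = 17),
      stringsAsFactors = FALSE)
  }
  load_pathways(do.call(rbind, rows))
}

#' Precision-at-k and AUC of planted-association recovery
#'
#' `precision_at_k[C]` is the fraction of the top-`k` proteins of category
#' `C` (by combined score, ties broken lexicographically) that were planted
#' in `C`. `auc` is the probability that a uniformly random planted
#' (protein, category) pair outscores a random non-planted pair, ties
#' counting one half (computed from midranks).
#'
#' @param scores a `score_matrix` computed on a synthetic corpus.
#' @param truth ground-truth list with element `planted`.
#' @param k cutoff; must not exceed the number of proteins.
#' @return List: `precision_at_k` (named per category), `auc`.
#' @export
evaluate_recovery <- function(scores, truth, k) {
  if (k > length(scores$proteins)) {
    stopf("k = %d exceeds the number of proteins (%d)",
          k, length(scores$proteins))
  }
  planted <- truth$planted
  prec <- vapply(scores$categories, function(C) {
    top <- rank_proteins(scores, C)$protein_id[seq_len(k)]
    mean(top %in% planted$protein_id[planted$category == C])
  }, numeric(1))
  is_planted <- matrix(FALSE, length(scores$proteins),
                       length(scores$categories),
                       dimnames = list(scores$proteins, scores$categories))
  keep <- planted$category %in% scores$categories &
    planted$protein_id %in% scores$proteins
  is_planted[cbind(planted$protein_id[keep], planted$category[keep])] <- TRUE
  s <- as.vector(scores$score)
  y <- as.vector(is_planted)
  n1 <- sum(y); n0 <- sum(!y)
  auc <- if (n1 == 0 || n0 == 0) NA_real_ else {
    r <- rank(s)
    (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  list(precision_at_k = prec, auc = auc)
}

#' Run the full synthetic pipeline end to end
#'
#' Generates vocabularies, corpus and pathways, runs matching, cube
#' construction, aggregation, CaseOLAP scoring and knowledge-graph assembly,
#' and returns every intermediate product. Deterministic given the
#' configuration (including its seed).
#'
#' @param config a `synth_config`.
#' @param with_kg also build the knowledge graph (default TRUE).
#' @return List: `vocab`, `corpus`, `truth`, `cube`, `index`, `counts`,
#'   `scores`, `pathways`, and (if requested) `kg`.
#' @export
synthetic_pipeline <- function(config, with_kg = TRUE) {
  vocab <- generate_vocabulary(config)
  gen <- generate_corpus(config, vocab)
  pathways <- generate_pathways(config, vocab$proteins)
  expanded <- expand_categories(vocab$categories, vocab$mesh)
  cube <- build_text_cube(gen$corpus, expanded, vocab$os)
  matcher <- compile_matcher(vocab$proteins)
  index <- index_mentions(gen$corpus, matcher)
  counts <- aggregate_counts(cube, index, vocab$proteins$protein_id)
  scores <- compute_score_matrix(counts)
  out <- list(vocab = vocab, corpus = gen$corpus, truth = gen$truth,
              cube = cube, index = index, counts = counts, scores = scores,
              pathways = pathways)
  if (with_kg) {
    out$kg <- build_knowledge_graph(gen$corpus, cube, index, vocab$proteins,
                                    vocab$mesh, vocab$os, pathways)
  }
  out
}
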
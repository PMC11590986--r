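test_that("graph assembly matches the hand enumeration", {
  fx <- micro_fixture()
  kg <- fx$kg
  expect_equal(sum(kg$nodes$type == "document"), 4L)
  expect_equal(sum(kg$nodes$type == "protein"), 2L)
  expect_equal(sum(kg$nodes$type == "mesh"), 3L)
  expect_equal(sum(kg$edges$type == "mentions"), 4L)
  expect_equal(sum(kg$edges$type == "assigns"), 5L)
  expect_equal(sum(kg$edges$type == "contains"), 0L)
  # mentions edge count = number of (doc, protein) pairs with positive count
  expect_equal(sum(kg$edges$type == "mentions"),
               sum(lengths(fx$index) > 0) + 1L)  # d2 mentions two proteins
  expect_equal(kg$n_dropped_assigns, 0L)

  # a MeSH id outside the vocabularies is dropped and counted
  rec <- fx$corpus
  rec$mesh_ids[[1]] <- c("D001", "DUNKNOWN")
  kg2 <- build_knowledge_graph(rec, fx$cube, fx$index, fx$proteins,
                               fx$mesh, fx$os)
  expect_equal(kg2$n_dropped_assigns, 1L)
  expect_equal(sum(kg2$edges$type == "assigns"), 5L)

  # mention of a protein outside the entity list is an error
  idx <- fx$index
  idx[["d1"]] <- c(idx[["d1"]], PX = 1L)
  expect_error(build_knowledge_graph(fx$corpus, fx$cube, idx, fx$proteins,
                                     fx$mesh, fx$os), "unknown protein")
})

test_that("pathway membership becomes contains edges within the entity set", {
  fx <- micro_fixture()
  pw <- load_pathways(data.frame(
    pathway_id = c("R1", "R2"), name = c("a", "b"), parent_id = "",
    member_protein_ids = c("P1|P2|PX", ""), p_value = c("0.1", "0.2")))
  kg <- build_knowledge_graph(fx$corpus, fx$cube, fx$index, fx$proteins,
                              fx$mesh, fx$os, pw)
  expect_equal(sum(kg$edges$type == "contains"), 2L)
  expect_equal(kg$n_dropped_members, 1L)
  expect_equal(sum(kg$nodes$type == "pathway"), 2L)
})

test_that("bulk CSV and GraphML exports round-trip the graph", {
  fx <- micro_fixture()
  for (fmt in c("bulk_csv", "graphml")) {
    dir <- tempfile()
    export_graph(fx$kg, dir, fmt)
    back <- import_graph(dir, fmt)
    key <- function(kg) {
      list(nodes = kg$nodes[order(kg$nodes$id),
                            c("id", "type", "name", "is_os")],
           edges = kg$edges[order(kg$edges$source, kg$edges$target,
                                  kg$edges$type), ])
    }
    a <- key(fx$kg); b <- key(back)
    expect_equal(a$nodes, b$nodes, ignore_attr = TRUE)
    expect_equal(a$edges, b$edges, ignore_attr = TRUE)
  }
})

test_that("the micro-fixture bulk export holds 9 edge rows in total", {
  fx <- micro_fixture()
  dir <- tempfile()
  export_graph(fx$kg, dir, "bulk_csv")
  efiles <- list.files(dir, "^edges_", full.names = TRUE)
  rows <- sum(vapply(efiles, function(p) nrow(read.csv(p)), numeric(1)))
  expect_equal(rows, 9)
  nheader <- read.csv(list.files(dir, "^nodes_", full.names = TRUE)[1],
                      check.names = FALSE)
  expect_true(all(c("id:ID", ":LABEL") %in% names(nheader)))
})

test_that("protein-OS co-occurrence traverses shared documents", {
  fx <- micro_fixture()
  cooc <- protein_os_cooccurrence(fx$kg)
  expect_equal(cooc$protein_id, c("P1", "P2"))
  expect_equal(cooc$os_descriptor_id, c("D100", "D100"))
  expect_equal(cooc$n_docs, c(1L, 1L))

  # permuting the corpus leaves the counts unchanged
  perm <- fx$corpus[c(4, 2, 3, 1), ]
  cube2 <- build_text_cube(perm, fx$expanded, fx$os)
  kg2 <- build_knowledge_graph(perm, cube2, fx$index, fx$proteins,
                               fx$mesh, fx$os)
  expect_equal(protein_os_cooccurrence(kg2), cooc)

  # restricting the document universe can remove support
  expect_equal(nrow(protein_os_cooccurrence(fx$kg,
                                            within_docs = c("d1", "d3"))), 0)
})

test_that("OS-and-CVD protein counting needs both co-occurrence and score", {
  fx <- micro_fixture()
  cooc <- protein_os_cooccurrence(fx$kg)
  expect_equal(count_os_cvd_proteins(cooc, fx$scores), 2L)
  expect_equal(count_os_cvd_proteins(cooc[0, ], fx$scores), 0L)
  zero <- manual_scores(matrix(0, 2, 2,
                               dimnames = list(c("P1", "P2"), c("ARR", "CM"))))
  expect_equal(count_os_cvd_proteins(cooc, zero), 0L)
})

test_that("OS molecule scores are means of member CaseOLAP scores", {
  S <- matrix(c(0.8, 0.2, 0, 0), 2, 2,
              dimnames = list(c("P1", "P2"), c("ARR", "CM")))
  scores <- manual_scores(S)
  cooc <- data.frame(protein_id = c("P1", "P2"),
                     os_descriptor_id = "M1", n_docs = 1L)
  expect_equal(os_molecule_score(cooc, scores, "M1", "ARR"), 0.5)
  expect_equal(os_molecule_score(cooc, scores, "M1", "CM"), 0)
  one <- cooc[1, ]
  expect_equal(os_molecule_score(one, scores, "M1", "ARR"), 0.8)
  expect_true(is.na(os_molecule_score(cooc, scores, "M9", "ARR")))
})

test_that("pathway scores damp member means by 1 - p-value", {
  S <- matrix(c(0.4, 0.2), 2, 1, dimnames = list(c("P1", "P2"), "CCS"))
  scores <- manual_scores(S)
  pw <- load_pathways(data.frame(
    pathway_id = c("R0", "R1", "Rnone"), name = c("a", "b", "c"),
    parent_id = "", member_protein_ids = c("P1|P2", "P1|P2", "PX"),
    p_value = c("0.05", "1", "0.5")))
  expect_equal(pathway_score(pw, scores, "R0", "CCS"), 0.3 * 0.95,
               tolerance = 1e-12)
  expect_equal(pathway_score(pw, scores, "R1", "CCS"), 0)
  expect_true(is.na(pathway_score(pw, scores, "Rnone", "CCS")))
  pw0 <- pw; pw0$p_value[1] <- 0
  expect_equal(pathway_score(pw0, scores, "R0", "CCS"), 0.3)
  expect_error(pathway_score(pw, scores, "nope", "CCS"), "unknown pathway")
})

test_that("association tables emit rows only for supported entities", {
  fx <- micro_fixture()
  cooc <- protein_os_cooccurrence(fx$kg)
  tab <- score_os_molecules(cooc, fx$scores)
  expect_equal(unique(tab$entity_id), "D100")
  expect_true(all(tab$n_support_docs >= 1))
  expect_equal(nrow(tab), length(fx$scores$categories))

  pw <- load_pathways(data.frame(
    pathway_id = c("R1", "R2"), name = c("a", "b"), parent_id = "",
    member_protein_ids = c("P1", "PX"), p_value = c("0.1", "0.1")))
  ptab <- score_pathways(pw, fx$scores)
  expect_equal(unique(ptab$entity_id), "R1")  # R2 has no curated member
})

test_that("association scores agree with a direct-mean oracle", {
  cats <- c("ARR", "CCS", "CM")
  for (seed in 1:30) {
    set.seed(seed)
    nP <- sample(3:8, 1)
    prot <- sprintf("p%02d", seq_len(nP))
    S <- matrix(runif(nP * 3), nP, 3, dimnames = list(prot, cats))
    scores <- manual_scores(S)
    cooc <- data.frame(
      protein_id = sample(prot, 6, replace = TRUE),
      os_descriptor_id = sample(c("M1", "M2"), 6, replace = TRUE),
      n_docs = sample(1:4, 6, replace = TRUE))
    for (m in unique(cooc$os_descriptor_id)) {
      for (C in cats) {
        expect_equal(os_molecule_score(cooc, scores, m, C),
                     oracle_os_score(cooc, scores, m, C),
                     tolerance = 1e-12)
      }
    }
    members <- sample(prot, sample(2:nP, 1))
    p_val <- sample(c(0, 1, runif(1)), 1)
    pw <- load_pathways(data.frame(
      pathway_id = "R1", name = "r", parent_id = "",
      member_protein_ids = paste(members, collapse = "|"),
      p_value = format(p_val, digits = 17)))
    for (C in cats) {
      expect_equal(pathway_score(pw, scores, "R1", C),
                   oracle_pathway_score(members, p_val, scores, C),
                   tolerance = 1e-12)
    }
  }
})

test_that("overlap tables cross OS phases with disease categories", {
  fx <- micro_fixture()
  ov <- overlap_tables(fx$cube, fx$index, fx$scores)
  expect_equal(ov$documents["MOS", "ARR"], 1L)
  expect_equal(ov$documents["MOS", "CM"], 0L)
  expect_true(all(ov$documents[c("IOS", "OOS"), ] == 0))
  # d2 mentions P1 and P2; both have positive ARR scores
  expect_equal(ov$proteins["MOS", "ARR"], 2L)
  expect_true(all(ov$proteins <= fx$scores$n_scoring))

  no_os <- fx$cube
  no_os$os_docs <- lapply(no_os$os_docs, function(x) character(0))
  ov2 <- overlap_tables(no_os, fx$index, fx$scores)
  expect_true(all(ov2$documents == 0) && all(ov2$proteins == 0))
})
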
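test_that("neighbourhoods are undirected across all edge types", {
  fx <- micro_fixture()
  pw <- load_pathways(data.frame(
    pathway_id = "R1", name = "r", parent_id = "",
    member_protein_ids = "P1", p_value = "0.1"))
  kg <- build_knowledge_graph(fx$corpus, fx$cube, fx$index, fx$proteins,
                              fx$mesh, fx$os, pw)
  # P1 is mentioned by d1 and d2 and contained in one pathway
  expect_setequal(kg_neighbors(kg, "P1"), c("d1", "d2", "R1"))
  expect_length(kg_neighbors(kg, "D002"), 2)  # d3, d4
  expect_error(kg_neighbors(kg, "nope"), "unknown node")
  # symmetry
  for (nb in kg_neighbors(kg, "P1")) {
    expect_true("P1" %in% kg_neighbors(kg, nb))
  }
})

test_that("pair scores reproduce the hand-computed cases", {
  fx <- micro_fixture()
  kg <- fx$kg
  # P1 and D100 share d2 only; d2 has degree 4 (D001, D100, P1, P2)
  expect_equal(pair_score(kg, "P1", "D100", "common_neighbors"), 1)
  expect_equal(pair_score(kg, "P1", "D100", "adamic_adar"), 1 / log(4))
  expect_equal(pair_score(kg, "P1", "D100", "resource_allocation"), 1 / 4)
  # P2 vs D001: common neighbour d2 as well
  expect_equal(pair_score(kg, "P2", "D001", "common_neighbors"), 1)
  # no common neighbours
  expect_equal(pair_score(kg, "P1", "D002", "common_neighbors"), 0)
  expect_equal(pair_score(kg, "P1", "D002", "adamic_adar"), 0)
  expect_equal(pair_score(kg, "P1", "D002", "resource_allocation"), 0)
  # preferential attachment is the degree product: P1 in {d1,d2}, D002 in {d3,d4}
  expect_equal(pair_score(kg, "P1", "D002", "preferential_attachment"), 4)
  expect_error(pair_score(kg, "P1", "P1"), "distinct")
  expect_error(pair_score(kg, "P1", "P2", "bogus"))
})

test_that("a single degree-2 common neighbour gives AA = 1/ln 2", {
  kg <- structure(list(
    nodes = data.frame(id = c("a", "b", "w"),
                       type = c("protein", "mesh", "document"),
                       name = c("a", "b", "w"),
                       is_os = c(FALSE, TRUE, FALSE)),
    edges = data.frame(source = c("w", "w"), target = c("a", "b"),
                       type = c("mentions", "assigns"),
                       count = c(1L, NA_integer_)),
    n_dropped_assigns = 0L, n_dropped_members = 0L),
    class = "knowledge_graph")
  expect_equal(pair_score(kg, "a", "b", "adamic_adar"), 1 / log(2),
               tolerance = 1e-12)
})

test_that("all measures agree with brute-force enumeration on random graphs", {
  for (seed in 1:25) {
    kg <- random_schema_kg(seed, n_prot = sample(2:5, 1),
                           n_doc = sample(5:15, 1),
                           n_mesh = sample(2:6, 1))
    A <- bf_adjacency_matrix(kg)
    prot <- kg$nodes$id[kg$nodes$type == "protein"]
    mesh <- kg$nodes$id[kg$nodes$type == "mesh"]
    for (m in c("common_neighbors", "adamic_adar", "resource_allocation",
                "preferential_attachment")) {
      tab <- rank_candidate_pairs(kg, "protein", "mesh", m)
      expect_equal(nrow(tab), length(prot) * length(mesh))
      for (i in seq_len(nrow(tab))) {
        expect_equal(
          tab$score[[i]],
          unname(bf_pair_score(A, tab$node_a[[i]], tab$node_b[[i]], m)),
          tolerance = 1e-12)
      }
      expect_true(all(diff(tab$score) <= 0))
    }
  }
})

test_that("protein-mesh common neighbours are documents of degree >= 2", {
  for (seed in 1:10) {
    kg <- random_schema_kg(seed)
    A <- bf_adjacency_matrix(kg)
    deg <- rowSums(A)
    prot <- kg$nodes$id[kg$nodes$type == "protein"]
    mesh <- kg$nodes$id[kg$nodes$type == "mesh"]
    for (p in prot) for (m in mesh) {
      common <- names(which(A[p, ] == 1 & A[m, ] == 1))
      if (length(common) > 0) {
        expect_true(all(kg$nodes$type[match(common, kg$nodes$id)] ==
                          "document"))
        expect_true(all(deg[common] >= 2))
      }
    }
  }
})

test_that("ranking covers the full candidate product with lexicographic ties", {
  kg <- random_schema_kg(7, n_prot = 2, n_mesh = 2, n_doc = 6)
  tab <- rank_candidate_pairs(kg, "protein", "mesh", "common_neighbors")
  expect_equal(nrow(tab), 4)
  ties <- split(seq_len(nrow(tab)), tab$score)
  for (idx in ties) {
    keys <- paste(tab$node_a[idx], tab$node_b[idx])
    expect_equal(keys, sort(keys))
  }
  # node insertion order must not matter
  kg2 <- kg
  perm <- sample(nrow(kg2$nodes))
  kg2$nodes <- kg2$nodes[perm, ]
  expect_equal(rank_candidate_pairs(kg2, "protein", "mesh",
                                    "common_neighbors"), tab)

  # isolated mesh nodes score zero everywhere
  kg3 <- kg
  kg3$edges <- kg3$edges[kg3$edges$type != "assigns", ]
  tab3 <- rank_candidate_pairs(kg3, "protein", "mesh", "adamic_adar")
  expect_true(all(tab3$score == 0))
})

test_that("a direct edge between candidate types is rejected", {
  kg <- random_schema_kg(3)
  bad <- kg
  bad$edges <- rbind(bad$edges, data.frame(
    source = bad$nodes$id[bad$nodes$type == "protein"][1],
    target = bad$nodes$id[bad$nodes$type == "mesh"][1],
    type = "assigns", count = NA_integer_))
  expect_error(rank_candidate_pairs(bad, "protein", "mesh"),
               "candidate universe violated")
})

test_that("adding a common-neighbour document never lowers CN, AA or RA", {
  for (seed in 1:10) {
    kg <- random_schema_kg(seed)
    prot <- kg$nodes$id[kg$nodes$type == "protein"][1]
    mesh <- kg$nodes$id[kg$nodes$type == "mesh"][1]
    kg2 <- kg
    kg2$nodes <- rbind(kg2$nodes, data.frame(
      id = "dnew", type = "document", name = "dnew", is_os = FALSE))
    kg2$edges <- rbind(kg2$edges, data.frame(
      source = c("dnew", "dnew"), target = c(prot, mesh),
      type = c("mentions", "assigns"), count = c(1L, NA_integer_)))
    for (m in c("common_neighbors", "adamic_adar", "resource_allocation")) {
      expect_gte(pair_score(kg2, prot, mesh, m),
                 pair_score(kg, prot, mesh, m))
    }
  }
})

test_that("the Adamic-Adar scores cross-check against igraph", {
  kg <- random_schema_kg(11, n_prot = 3, n_doc = 10, n_mesh = 4)
  g <- as_igraph(kg)
  prot <- kg$nodes$id[kg$nodes$type == "protein"]
  mesh <- kg$nodes$id[kg$nodes$type == "mesh"]
  sim <- igraph::similarity(g, method = "invlogweighted")
  rownames(sim) <- colnames(sim) <- igraph::V(g)$name
  for (p in prot) for (m in mesh) {
    expect_equal(pair_score(kg, p, m, "adamic_adar"), sim[p, m],
                 tolerance = 1e-12)
  }
})

test_that("wide matrix export mirrors the long table", {
  kg <- random_schema_kg(5)
  tab <- rank_candidate_pairs(kg, "protein", "mesh", "resource_allocation")
  m <- pair_score_matrix(tab)
  for (i in seq_len(nrow(tab))) {
    expect_equal(m[tab$node_a[[i]], tab$node_b[[i]]], tab$score[[i]])
  }
})
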
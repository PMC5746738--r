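test_that("shortest-path distances are exact under edge distances", {
  # unit-weight path r1 - r2 - r3
  model <- chain_model(3)
  rg <- build_reaction_graph(build_bipartite(model), weighted = FALSE)
  D <- shortest_path_distances(rg)
  expect_equal(D["r1", "r3"], 2)
  expect_equal(D["r1", "r2"], 1)

  # weighted two-hop: 0.2 + 0.25
  adj <- matrix(0, 3, 3); adj[1, 2] <- adj[2, 1] <- 0.2
  adj[2, 3] <- adj[3, 2] <- 0.25
  Dw <- shortest_path_distances(rg_from_adjacency(adj))
  expect_equal(Dw["R1", "R3"], 0.45)

  # triangle with unit weights: direct edges dominate
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  Dt <- shortest_path_distances(rg_from_adjacency(tri))
  expect_true(all(Dt[upper.tri(Dt)] == 1))

  # disconnected input is refused
  disc <- matrix(0, 3, 3); disc[1, 2] <- disc[2, 1] <- 1
  expect_error(shortest_path_distances(rg_from_adjacency(disc)),
               "not connected")
})

test_that("B-matrix follows the rank-linear convention on hand-worked cases", {
  # unit path A-B-C: V for (A,B) is {2, 1, 1}, midrank of 1 is 1.5 -> 0.5;
  # V for (A,C) is {1, 1, 2}, rank of 2 is 3 -> -1
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3,
              dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  B <- build_b_matrix(D)
  expect_equal(B["A", "B"], 0.5)
  expect_equal(B["B", "C"], 0.5)
  expect_equal(B["A", "C"], -1)
  expect_identical(B, t(B))
  expect_true(all(diag(B) == 0))
  expect_true(all(B >= -1 & B <= 1))

  # full ties map to the midpoint 0
  Dt <- matrix(1, 4, 4); diag(Dt) <- 0
  expect_true(all(build_b_matrix(Dt)[upper.tri(Dt)] == 0))

  # a pair strictly closer than everything else gets +1
  Dc <- matrix(c(0, 0.1, 5, 6,
                 0.1, 0, 5, 6,
                 5, 5, 0, 7,
                 6, 6, 7, 0), 4, 4)
  expect_equal(build_b_matrix(Dc)[1, 2], 1)

  # two-node component degenerates to B = 1
  D2 <- matrix(c(0, 3, 3, 0), 2, 2)
  expect_equal(build_b_matrix(D2)[1, 2], 1)
})

test_that("value-linear alternative convention interpolates by distance", {
  D <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  B <- build_b_matrix(D, convention = "value")
  # pair (1,2): V = {2, 1, 1}; d = 1 is the minimum -> +1
  expect_equal(B[1, 2], 1)
  # pair (1,3): V = {1, 1, 2}; d = 2 is the maximum -> -1
  expect_equal(B[1, 3], -1)
  Dt <- matrix(1, 3, 3); diag(Dt) <- 0
  expect_true(all(build_b_matrix(Dt, "value")[upper.tri(Dt)] == 0))
})

test_that("modularity Q is the plain signed double sum", {
  B <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(modularity_q(B, c(1, 1)), sum(B))
  expect_equal(modularity_q(B, c(1, -1)), -2)
  expect_equal(modularity_q(matrix(0, 3, 3), c(1, -1, 1)), 0)
})

test_that("leading-eigenvector split matches 2x2 analysis and block structure", {
  # B = [[0,1],[1,0]]: leading eigenvector (1,1)/sqrt(2) -> no split
  res <- leading_eigenvector_split(matrix(c(0, 1, 1, 0), 2, 2))
  expect_false(res$split_found)

  # planted blocks {1,2} vs {3,4}: eigen split equals the brute-force argmax
  B <- matrix(-0.9, 4, 4); B[1:2, 1:2] <- 0.9; B[3:4, 3:4] <- 0.9; diag(B) <- 0
  res <- leading_eigenvector_split(B)
  expect_true(res$split_found)
  expect_gt(res$q, 0)
  oracle <- brute_force_best_split(B)
  expect_equal(res$q, oracle$q)
  expect_true(identical(res$s, oracle$s) || identical(res$s, -oracle$s))

  # zero matrix: Q = 0 -> terminate
  expect_false(leading_eigenvector_split(matrix(0, 3, 3))$split_found)
})

test_that("eigen split never beats the exhaustive bipartition oracle", {
  set.seed(99)
  for (k in 1:40) {
    rg <- random_weighted_rg(sample(4:9, 1))
    B <- build_b_matrix(shortest_path_distances(rg))
    res <- leading_eigenvector_split(B)
    oracle <- brute_force_best_split(B)
    expect_lte(res$q, oracle$q + 1e-9)
    if (res$split_found) expect_gt(res$q, 0)
  }
})

test_that("two triangles joined by a long bridge split at the bridge", {
  adj <- matrix(0, 6, 6)
  for (p in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))) {
    adj[p[1], p[2]] <- adj[p[2], p[1]] <- 1
  }
  adj[3, 4] <- adj[4, 3] <- 5
  rg <- rg_from_adjacency(adj)
  tree <- recursive_partition(rg)
  root <- tree$modules[[1]]
  expect_length(root$children, 2)
  kid_sets <- lapply(tree$modules[root$children], function(m) sort(m$reaction_ids))
  kid_sets <- kid_sets[order(vapply(kid_sets, `[`, "", 1))]
  expect_identical(kid_sets, list(paste0("R", 1:3), paste0("R", 4:6)))
  # both triangles are terminal: tree is root + 2 leaves
  expect_length(tree$modules, 3)
  # the split agrees with the exhaustive max-Q bipartition of the 6 nodes
  B <- build_b_matrix(shortest_path_distances(rg))
  oracle <- brute_force_best_split(B)
  expect_identical(sort(rg$reaction_ids[oracle$s > 0]), paste0("R", 1:3))
})

test_that("a two-node component is terminal", {
  adj <- matrix(c(0, 1, 1, 0), 2, 2)
  tree <- recursive_partition(rg_from_adjacency(adj))
  expect_length(tree$modules, 1)
  expect_length(tree$modules[[1]]$children, 0)
})

test_that("each connected component seeds its own root", {
  adj <- matrix(0, 5, 5)
  adj[1, 2] <- adj[2, 1] <- 1
  adj[3, 4] <- adj[4, 3] <- 1; adj[4, 5] <- adj[5, 4] <- 1; adj[3, 5] <- adj[5, 3] <- 1
  tree <- recursive_partition(rg_from_adjacency(adj))
  roots <- which(vapply(tree$modules, function(m) is.na(m$parent), TRUE))
  expect_length(roots, 2)
  expect_setequal(unlist(lapply(tree$modules[roots], `[[`, "reaction_ids")),
                  paste0("R", 1:5))
})

test_that("tree invariants hold and trees are deterministic on synthetic runs", {
  for (s in c(2, 12)) {
    res <- run_synthetic_pipeline(synthetic_spec(seed = s))
    expect_tree_invariants(res$tree)
    res2 <- run_synthetic_pipeline(synthetic_spec(seed = s))
    expect_identical(as.data.frame(res$tree), as.data.frame(res2$tree))
  }
})

test_that("annotation computes density, height and baseline flags", {
  toy <- toy_network()
  rs <- reaction_scores(toy$model, toy$ssm_nodes)
  rg <- build_reaction_graph(build_bipartite(toy$model), rs)
  tree <- annotate_tree(recursive_partition(rg), toy$model, toy$ssm_nodes)
  df <- as.data.frame(tree)
  expect_true(all(df$height[df$n_children == 0] == 0))
  # {R1, R2} touch the five SSM nodes: density 2.5, baseline
  pair <- df[df$reaction_ids %in% c("R1;R2", "R2;R1"), ]
  expect_equal(pair$ssm_density, 2.5)
  expect_true(pair$baseline)
  # SSM-free modules have density 0 and fail the baseline criteria
  expect_true(all(!df$baseline[df$ssm_count == 0]))
  # density may exceed 1: five reactions touching six SSM nodes
  mets <- data.frame(node_id = paste0("s", 1:6, "[c]"),
                     base_name = paste0("s", 1:6), compartment = "c",
                     excluded = FALSE)
  mets <- rbind(mets, data.frame(node_id = paste0("l", 1:6, "[c]"),
                                 base_name = paste0("l", 1:6),
                                 compartment = "c", excluded = FALSE))
  rxns <- lapply(1:5, function(i) {
    list(id = paste0("R", i), reversible = FALSE,
         reactants = stats::setNames(c(1, 1), paste0(c(paste0("l", i), paste0("s", i)), "[c]")),
         products = stats::setNames(c(1, 1), paste0(c(paste0("l", i + 1), paste0("s", i + 1)), "[c]")),
         ec_number = NA_character_)
  })
  m5 <- mma:::new_metabolic_model("m5", "c", mets, rxns)
  rg5 <- build_reaction_graph(build_bipartite(m5),
                              reaction_scores(m5, paste0("s", 1:6, "[c]")))
  t5 <- annotate_tree(recursive_partition(rg5), m5, paste0("s", 1:6, "[c]"))
  root5 <- as.data.frame(t5)
  expect_equal(root5$ssm_density[is.na(root5$parent)], 6 / 5)
  expect_true(root5$baseline[is.na(root5$parent)])
})

test_that("module trees serialize to JSON and flat TSV", {
  res <- run_synthetic_pipeline(synthetic_spec(seed = 4))
  js <- withr::local_tempfile(fileext = ".json")
  write_module_tree_json(res$tree, js)
  parsed <- jsonlite::read_json(js)
  n_nodes <- function(x) 1 + sum(vapply(x$children, n_nodes, 0))
  expect_equal(sum(vapply(parsed, n_nodes, 0)), length(res$tree$modules))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_module_tree_tsv(res$tree, tsv)
  flat <- read.delim(tsv)
  expect_equal(nrow(flat), length(res$tree$modules))
  expect_true(all(c("module_id", "parent", "size", "height", "ssm_density",
                    "q_split", "reaction_ids") %in% names(flat)))
})
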
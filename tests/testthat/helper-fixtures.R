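# Fixtures built in code and independent oracles used across test files.

# --- tiny hand-written models -------------------------------------------

# linear chain: r_i converts a_i -> a_{i+1}; reaction graph is a path
chain_model <- function(n) {
  bases <- paste0("a", seq_len(n + 1))
  mets <- data.frame(node_id = paste0(bases, "[c]"), base_name = bases,
                     compartment = "c", excluded = FALSE,
                     stringsAsFactors = FALSE)
  reactions <- lapply(seq_len(n), function(i) {
    list(id = paste0("r", i), reversible = FALSE,
         reactants = stats::setNames(1, paste0("a", i, "[c]")),
         products = stats::setNames(1, paste0("a", i + 1, "[c]")),
         ec_number = NA_character_)
  })
  mma:::validate_model(mma:::new_metabolic_model(
    name = "chain", compartments = "c", metabolites = mets,
    reactions = reactions))
}

# JSON text for a 2-reaction, 3-metabolite model
tiny_model_json <- function(path, bad_ref = FALSE) {
  writeLines(sprintf('{
  "name": "tiny", "compartments": ["c", "m"],
  "metabolites": [
    {"id": "glc[c]", "base_name": "glc", "compartment": "c"},
    {"id": "g6p[c]", "base_name": "g6p", "compartment": "c"},
    {"id": "pyr[m]", "base_name": "pyr", "compartment": "m"}
  ],
  "reactions": [
    {"id": "HEX", "reversible": false, "stoich": {"glc[c]": -1, "g6p[c]": 1}},
    {"id": "PYRT", "reversible": true, "stoich": {"g6p[c]": -1, "%s": 2}}
  ]
}', if (bad_ref) "ghost[c]" else "pyr[m]"), path)
  path
}

sbml_fixture <- function(path) {
  writeLines('<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
  <model id="toy_sbml" name="toy_sbml">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="M_a" name="a" compartment="c" constant="false"/>
      <species id="M_b" name="b" compartment="c" constant="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="R_ab" reversible="true">
        <listOfReactants>
          <speciesReference species="M_a" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_b" stoichiometry="2" constant="true"/>
        </listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>', path)
  path
}

# reaction_graph built directly from a symmetric adjacency matrix
rg_from_adjacency <- function(adj, weighted = TRUE) {
  ids <- if (is.null(rownames(adj))) paste0("R", seq_len(nrow(adj))) else rownames(adj)
  dimnames(adj) <- list(ids, ids)
  structure(list(adjacency = adj, reaction_ids = ids,
                 rs = stats::setNames(integer(length(ids)), ids),
                 weighted = weighted),
            class = "reaction_graph")
}

random_weighted_rg <- function(n, p = 0.5) {
  repeat {
    adj <- matrix(0, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- stats::runif(1, 0.1, 1)
    }
    # keep only connected draws so distance matrices are finite
    g <- igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected")
    if (igraph::is_connected(g)) return(rg_from_adjacency(adj))
  }
}

# --- independent oracles -------------------------------------------------

# exhaustive maximum of Q = s' B s over all nontrivial sign vectors
brute_force_best_split <- function(B) {
  n <- nrow(B)
  best_q <- -Inf; best_s <- NULL
  for (mask in 0:(2^(n - 1) - 1)) {
    s <- c(1, ifelse(bitwAnd(mask, 2^(seq_len(n - 1) - 1)) > 0, 1, -1))
    if (length(unique(s)) < 2) next
    q <- drop(t(s) %*% B %*% s)
    if (q > best_q) { best_q <- q; best_s <- s }
  }
  list(q = best_q, s = best_s)
}

# connectivity of a node subset, straight BFS on the adjacency matrix
subset_connected <- function(adj, nodes) {
  idx <- match(nodes, rownames(adj))
  if (length(idx) == 1) return(TRUE)
  sub <- adj[idx, idx, drop = FALSE] > 0
  seen <- c(1L); frontier <- c(1L)
  while (length(frontier)) {
    nxt <- setdiff(which(colSums(sub[frontier, , drop = FALSE]) > 0), seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  length(seen) == length(idx)
}

# all connected k-subsets of a graph, by filtering combinations
enumerate_connected_subsets <- function(adj, k) {
  ids <- rownames(adj)
  sets <- utils::combn(ids, k, simplify = FALSE)
  Filter(function(s) subset_connected(adj, s), sets)
}

# structural invariants every module tree must satisfy
expect_tree_invariants <- function(tree) {
  for (m in tree$modules) {
    expect_gte(m$size, 1)
    expect_identical(m$size, length(m$reaction_ids))
    if (length(m$children)) {
      kids <- tree$modules[m$children]
      kid_sets <- lapply(kids, `[[`, "reaction_ids")
      expect_identical(sort(unlist(kid_sets)), sort(m$reaction_ids))
      expect_identical(sum(lengths(kid_sets)), length(m$reaction_ids))  # disjoint
      for (k in kids) expect_lt(k$size, m$size)
      if (!is.null(m$height)) {
        expect_identical(m$height,
                         1L + max(vapply(kids, `[[`, 0L, "height")))
      }
      if (!is.na(m$q_split)) expect_gt(m$q_split, 1e-12)
    } else {
      if (!is.null(m$height)) expect_identical(m$height, 0L)
      expect_true(is.na(m$q_split))
    }
    if (!is.na(m$parent)) {
      expect_true(m$module_id %in% tree$modules[[m$parent]]$children)
    }
  }
  invisible(tree)
}

# long-format metabolomics data.frame from named replicate vectors
make_dataset <- function(...) {
  groups <- list(...)
  do.call(rbind, lapply(names(groups), function(key) {
    parts <- strsplit(key, "\\.")[[1]]   # "<metabolite>.<timepoint>"
    data.frame(base_name = parts[1], timepoint = parts[2],
               replicate = seq_along(groups[[key]]),
               peak_area = groups[[key]], stringsAsFactors = FALSE)
  }))
}
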
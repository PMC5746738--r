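#' Shortest-path distance matrix over one connected component
#'
#' Exact Dijkstra all-pairs distances under the (non-negative) edge
#' distances of the reaction graph, restricted to a connected set of nodes.
#' Paths are taken in the graph induced by \code{component}.
#'
#' @param rg a \code{reaction_graph}.
#' @param component character vector of reaction ids forming one connected
#'   component (an error is raised otherwise -- split components first).
#' @return symmetric numeric matrix with zero diagonal and finite entries.
#' @export
shortest_path_distances <- function(rg, component = rg$reaction_ids) {
  g <- reaction_igraph(rg, component)
  d <- igraph::distances(g, weights = igraph::E(g)$weight, algorithm = "dijkstra")
  if (any(!is.finite(d))) {
    stop("node set is not connected; partition components before computing distances")
  }
  d[component, component, drop = FALSE]
}

#' Rank-linear B-matrix from a distance matrix
#'
#' For each node pair (i, j), the comparison vector V collects every
#' distance either endpoint is involved in -- D(i,x) and D(j,x) for all
#' other nodes x -- plus D(i,j) itself, so L = 2(n-2) + 1.  B(i,j) maps the
#' midrank r of D(i,j) in ascending-sorted V linearly onto [-1, 1]:
#' \deqn{B(i,j) = 1 - 2 (r - 1) / (L - 1),}
#' so the pair's shortest possible standing gives +1 and the longest -1.
#' Close pairs thus attract (+) and distant pairs repel (-) in the
#' modularity optimization.  A two-node component has L = 1 and gets
#' B(i,j) = 1 (which can never yield an accepted split).
#'
#' The alternative \code{convention = "value"} interpolates D(i,j) linearly
#' between min(V) and max(V) instead of using its rank (0 under full ties).
#'
#' Per-pair computations are independent; chunked evaluation over pair
#' subsets reproduces the serial result exactly.
#'
#' @param D distance matrix from [shortest_path_distances()].
#' @param convention \code{"rank"} (default) or \code{"value"}.
#' @return symmetric matrix with entries in [-1, 1] and zero diagonal.
#' @export
build_b_matrix <- function(D, convention = c("rank", "value")) {
  convention <- match.arg(convention)
  n <- nrow(D)
  B <- matrix(0, n, n, dimnames = dimnames(D))
  if (n < 2) return(B)
  if (n == 2) {
    B[1, 2] <- B[2, 1] <- 1
    return(B)
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      others <- setdiff(seq_len(n), c(i, j))
      d <- D[i, j]
      V <- c(D[i, others], D[j, others], d)
      if (convention == "rank") {
        L <- length(V)
        r <- sum(V < d) + (sum(V == d) + 1) / 2   # midrank of d in V
        b <- 1 - 2 * (r - 1) / (L - 1)
      } else {
        lo <- min(V); hi <- max(V)
        b <- if (hi > lo) 1 - 2 * (d - lo) / (hi - lo) else 0
      }
      B[i, j] <- B[j, i] <- b
    }
  }
  B
}

#' Modularity score Q of a signed bipartition
#'
#' \deqn{Q = \sum_i \sum_j B_{ij} s_i s_j}
#' over a +/-1 assignment s (the diagonal contributes 0 since B(i,i) = 0).
#' Unnormalized: only the sign of Q matters for the termination rule.
#'
#' @param B symmetric B-matrix.
#' @param s vector of +1/-1 of matching length.
#' @return numeric Q.
#' @export
modularity_q <- function(B, s) {
  stopifnot(length(s) == nrow(B), all(s %in% c(-1, 1)))
  drop(t(s) %*% B %*% s)
}

#' Leading-eigenvector binary split
#'
#' Computes the eigenvector of B with the largest eigenvalue (dense
#' symmetric decomposition -- deterministic at the component sizes the
#' recursion produces) and signs nodes by its entries: positive entries
#' +1, negative -1.  Sign-ambiguity of the eigenvector is removed by
#' orienting its first nonzero entry positive; entries that are zero
#' (|v| < 1e-12) are assigned +1.  The split is rejected when all signs
#' agree or when Q fails to exceed the floating-point guard \code{tol}.
#'
#' @param B symmetric B-matrix.
#' @param tol strict positivity guard for Q (default 1e-12).
#' @return list with \code{s} (signs), \code{q}, \code{split_found}.
#' @export
leading_eigenvector_split <- function(B, tol = 1e-12) {
  n <- nrow(B)
  if (n < 2) return(list(s = rep(1, n), q = 0, split_found = FALSE))
  v <- eigen(B, symmetric = TRUE)$vectors[, 1]
  nz <- which(abs(v) >= 1e-12)
  if (length(nz) && v[nz[1]] < 0) v <- -v
  s <- ifelse(abs(v) < 1e-12, 1, sign(v))
  q <- modularity_q(B, s)
  list(s = s, q = q, split_found = length(unique(s)) == 2 && q > tol)
}

#' Recursive hierarchical partition of a reaction graph
#'
#' Each connected component of the graph seeds one root module.  For the
#' current module, the shortest-path distance matrix and B-matrix are
#' recomputed restricted to its nodes and a leading-eigenvector split is
#' attempted; on success two child modules are created (Q of the split is
#' recorded on the parent), each child is then divided into its connected
#' sub-networks (each becoming a further tree node when the child is
#' disconnected), and the recursion continues.  A module whose split is
#' rejected (all one sign, or Q <= 0) is terminal.  Every module ever
#' instantiated appears in the tree.
#'
#' @param rg a \code{reaction_graph}.
#' @param b_convention passed to [build_b_matrix()].
#' @return a \code{module_tree}: list of module records (\code{module_id},
#'   \code{parent}, \code{children}, \code{reaction_ids}, \code{size},
#'   \code{q_split}), ordered by module_id.  Annotate with
#'   [annotate_tree()].
#' @export
recursive_partition <- function(rg, b_convention = "rank") {
  modules <- list()
  add_module <- function(nodes, parent) {
    id <- length(modules) + 1L
    modules[[id]] <<- list(module_id = id, parent = parent,
                           children = integer(0), reaction_ids = nodes,
                           size = length(nodes), q_split = NA_real_)
    if (!is.na(parent)) {
      modules[[parent]]$children <<- c(modules[[parent]]$children, id)
    }
    id
  }
  descend <- function(id) {
    force(id)   # id may be an add_module() call that must mutate `modules` first
    nodes <- modules[[id]]$reaction_ids
    if (length(nodes) < 2) return(invisible())
    D <- shortest_path_distances(rg, nodes)
    B <- build_b_matrix(D, convention = b_convention)
    res <- leading_eigenvector_split(B)
    if (!res$split_found) return(invisible())
    modules[[id]]$q_split <<- res$q
    for (sgn in c(1, -1)) {
      side <- nodes[res$s == sgn]
      child <- add_module(side, id)
      comps <- graph_components(rg, side)
      if (length(comps) > 1) {
        for (comp in comps) descend(add_module(comp, child))
      } else {
        descend(child)
      }
    }
    invisible()
  }
  for (comp in graph_components(rg)) {
    descend(add_module(comp, NA_integer_))
  }
  structure(list(modules = modules, weighted = rg$weighted), class = "module_tree")
}

#' Connected components of (a subgraph of) a reaction graph
#'
#' @param rg a \code{reaction_graph}.
#' @param nodes optional node subset (induced subgraph).
#' @return list of character vectors of reaction ids, one per component,
#'   in deterministic (first-seen index) order.
#' @export
graph_components <- function(rg, nodes = rg$reaction_ids) {
  g <- reaction_igraph(rg, nodes)
  memb <- igraph::components(g)$membership
  unname(split(names(memb), memb))
}

#' Annotate a module tree with SSM density, height and baseline flags
#'
#' SSM density of a module is the number of distinct SSM nodes produced or
#' consumed by the module's reactions divided by the module's reaction
#' count (it can exceed 1: five reactions can touch six SSM nodes).  Height
#' is the longest downward path to a terminal module (0 for leaves).  A
#' module meets the baseline criteria when it has at least two reactions
#' and SSM density greater than 0.5.
#'
#' @param tree a \code{module_tree}.
#' @param model the \code{metabolic_model} the graph was built from.
#' @param ssm_nodes character vector of SSM node ids.
#' @return the tree with \code{ssm_count}, \code{ssm_density},
#'   \code{height}, \code{baseline} filled per module.
#' @export
annotate_tree <- function(tree, model, ssm_nodes) {
  touched <- reaction_ssm_sets(model, ssm_nodes)
  heights <- rep(NA_integer_, length(tree$modules))
  height_of <- function(id) {
    if (!is.na(heights[id])) return(heights[id])
    ch <- tree$modules[[id]]$children
    h <- if (!length(ch)) 0L else 1L + max(vapply(ch, height_of, 0L))
    heights[id] <<- h
    h
  }
  for (i in seq_along(tree$modules)) {
    m <- tree$modules[[i]]
    ssms <- unique(unlist(touched[m$reaction_ids], use.names = FALSE))
    tree$modules[[i]]$ssm_count <- length(ssms)
    tree$modules[[i]]$ssm_density <- length(ssms) / m$size
    tree$modules[[i]]$height <- height_of(i)
    tree$modules[[i]]$baseline <- m$size >= 2 && length(ssms) / m$size > 0.5
  }
  tree
}

# per-reaction sets of SSM nodes touched (excluded metabolites cannot count)
reaction_ssm_sets <- function(model, ssm_nodes) {
  keep <- model$metabolites$node_id[!model$metabolites$excluded]
  ssm <- intersect(unique(ssm_nodes), keep)
  out <- lapply(model$reactions, function(r) {
    intersect(union(names(r$reactants), names(r$products)), ssm)
  })
  stats::setNames(out, vapply(model$reactions, `[[`, "", "id"))
}

#' Flatten a module tree to a data.frame
#'
#' @param x a \code{module_tree}.
#' @param ... unused.
#' @return data.frame with one row per module (reaction ids
#'   semicolon-joined).
#' @export
as.data.frame.module_tree <- function(x, ...) {
  get0n <- function(m, f, default) if (is.null(m[[f]])) default else m[[f]]
  data.frame(
    module_id = vapply(x$modules, `[[`, 0L, "module_id"),
    parent = vapply(x$modules, `[[`, 0L, "parent"),
    size = vapply(x$modules, `[[`, 0L, "size"),
    n_children = vapply(x$modules, function(m) length(m$children), 0L),
    height = vapply(x$modules, get0n, 0L, f = "height", default = NA_integer_),
    ssm_count = vapply(x$modules, get0n, 0L, f = "ssm_count", default = NA_integer_),
    ssm_density = vapply(x$modules, get0n, 0, f = "ssm_density", default = NA_real_),
    baseline = vapply(x$modules, get0n, NA, f = "baseline", default = NA),
    q_split = vapply(x$modules, `[[`, 0, "q_split"),
    probability = vapply(x$modules, get0n, 0, f = "probability", default = NA_real_),
    reaction_ids = vapply(x$modules, function(m) paste(m$reaction_ids, collapse = ";"), ""),
    stringsAsFactors = FALSE
  )
}

#' @export
print.module_tree <- function(x, ...) {
  df <- as.data.frame(x)
  cat("Module tree: ", nrow(df), " modules (",
      sum(df$n_children == 0), " terminal, ",
      sum(is.na(df$parent)), " root components)",
      if (!is.null(x$weighted) && x$weighted) ", weighted graph" else "",
      "\n", sep = "")
  if (!all(is.na(df$baseline))) {
    cat("  baseline-criteria modules (size >= 2, SSM density > 0.5): ",
        sum(df$baseline, na.rm = TRUE), "\n", sep = "")
  }
  invisible(x)
}

#' Terminal (leaf) modules of a tree
#'
#' @param tree a \code{module_tree}.
#' @return integer vector of module ids with no children.
#' @export
terminal_modules <- function(tree) {
  which(vapply(tree$modules, function(m) length(m$children) == 0L, TRUE))
}

#' Baseline-criteria modules of an annotated tree
#'
#' @param tree an annotated \code{module_tree}.
#' @return integer vector of module ids with size >= 2 and SSM density
#'   > 0.5.
#' @export
baseline_modules <- function(tree) {
  flags <- vapply(tree$modules, function(m) isTRUE(m$baseline), TRUE)
  if (all(is.na(flags))) stop("tree is not annotated; run annotate_tree()")
  which(flags)
}

#' Serialize a module tree
#'
#' JSON keeps the full hierarchy (nested children) with annotations; TSV is
#' the flat per-module table of [as.data.frame.module_tree()].
#'
#' @param tree a \code{module_tree}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_module_tree_json <- function(tree, path) {
  nest <- function(id) {
    m <- tree$modules[[id]]
    rec <- m[setdiff(names(m), c("children", "parent"))]
    rec$children <- lapply(m$children, nest)
    rec
  }
  roots <- which(vapply(tree$modules, function(m) is.na(m$parent), TRUE))
  jsonlite::write_json(lapply(roots, nest), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_module_tree_json
#' @export
write_module_tree_tsv <- function(tree, path) {
  utils::write.table(as.data.frame(tree), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
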
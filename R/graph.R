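#' Build the directed bipartite reaction-metabolite graph
#'
#' Directed connectivity over N reaction nodes plus M metabolite nodes:
#' reaction -> metabolite when the metabolite is a product, metabolite ->
#' reaction when it is a reactant; a reversible reaction contributes both
#' orientations.  Metabolites flagged excluded contribute no edges (they
#' remain as isolated nodes).
#'
#' @param model a \code{metabolic_model} with exclusions applied.
#' @return a \code{bipartite_graph}: list with \code{reaction_ids},
#'   \code{metabolite_ids}, and per-reaction character vectors
#'   \code{produced} / \code{consumed} of non-excluded node ids (with
#'   reversibility already folded in: a reversible reaction produces and
#'   consumes every metabolite on either side).
#' @export
build_bipartite <- function(model) {
  keep <- model$metabolites$node_id[!model$metabolites$excluded]
  produced <- vector("list", length(model$reactions))
  consumed <- vector("list", length(model$reactions))
  for (i in seq_along(model$reactions)) {
    r <- model$reactions[[i]]
    p <- intersect(names(r$products), keep)
    c_ <- intersect(names(r$reactants), keep)
    if (r$reversible) {
      both <- union(p, c_)
      produced[[i]] <- both
      consumed[[i]] <- both
    } else {
      produced[[i]] <- p
      consumed[[i]] <- c_
    }
  }
  structure(
    list(reaction_ids = vapply(model$reactions, `[[`, "", "id"),
         metabolite_ids = model$metabolites$node_id,
         excluded = model$metabolites$excluded,
         produced = produced, consumed = consumed),
    class = "bipartite_graph"
  )
}

#' Convert a bipartite graph to an igraph object
#'
#' Directed graph with reaction and metabolite node types (for GraphML/SIF
#' export and visualization).
#'
#' @param bg a \code{bipartite_graph}.
#' @return an igraph with vertex attributes \code{type}
#'   (\code{"reaction"}/\code{"metabolite"}).
#' @export
bipartite_igraph <- function(bg) {
  edges <- character(0)
  for (i in seq_along(bg$reaction_ids)) {
    rid <- bg$reaction_ids[i]
    if (length(bg$produced[[i]])) {
      edges <- c(edges, rbind(rid, bg$produced[[i]]))
    }
    if (length(bg$consumed[[i]])) {
      edges <- c(edges, rbind(bg$consumed[[i]], rid))
    }
  }
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(c(bg$reaction_ids, bg$metabolite_ids),
                     type = c(rep("reaction", length(bg$reaction_ids)),
                              rep("metabolite", length(bg$metabolite_ids))))
  if (length(edges)) g <- g + igraph::edges(edges)
  g
}

#' Reaction scores from SSM participation
#'
#' The reaction score RS of a reaction is the number of distinct SSM nodes
#' it either produces or consumes (set semantics: a metabolite on both
#' sides counts once; stoichiometric multiplicity is chemistry, not
#' evidence).  Excluded metabolites never count.
#'
#' @param model a \code{metabolic_model} with exclusions applied.
#' @param ssm_nodes character vector of SSM node ids (see
#'   [expand_to_model()]).
#' @return integer vector of length N, named by reaction id.
#' @export
reaction_scores <- function(model, ssm_nodes) {
  keep <- model$metabolites$node_id[!model$metabolites$excluded]
  ssm <- intersect(unique(ssm_nodes), keep)
  rs <- vapply(model$reactions, function(r) {
    length(intersect(union(names(r$reactants), names(r$products)), ssm))
  }, 0L)
  stats::setNames(rs, vapply(model$reactions, `[[`, "", "id"))
}

#' Build the SSM-weighted reaction-centric graph
#'
#' Undirected graph over the N reactions.  Reactions i and j are adjacent
#' when some non-excluded metabolite produced by one is consumed by the
#' other (either orientation; reversibility was folded into the bipartite
#' graph).  In the weighted graph the edge distance is the reciprocal of
#' the summed reaction scores, \eqn{RG(i,j) = 1 / (RS_i + RS_j)}, so
#' reaction pairs dense in SSMs sit close together; pairs with
#' \eqn{RS_i + RS_j = 0} get distance 1.0, the supremum of the formula over
#' scored pairs.  Unweighted graphs assign every edge distance 1.0.  The
#' edge \emph{set} is identical in both cases; only distances differ.
#'
#' The pair scan is chunk-decomposable: \code{chunks} splits the i-index
#' range into independent blocks whose union is bit-identical to the serial
#' scan (so the O(N^2) work can be distributed externally).
#'
#' @param bg a \code{bipartite_graph}.
#' @param rs reaction-score vector from [reaction_scores()] (required when
#'   \code{weighted}; zeros assumed otherwise).
#' @param weighted logical.
#' @param chunks integer; number of row blocks for the pair scan.
#' @return a \code{reaction_graph}: list with the symmetric N x N distance
#'   \code{adjacency} matrix (0 = no edge), \code{reaction_ids}, \code{rs},
#'   \code{weighted}.
#' @export
build_reaction_graph <- function(bg, rs = NULL, weighted = TRUE, chunks = 1L) {
  n <- length(bg$reaction_ids)
  if (is.null(rs)) rs <- stats::setNames(integer(n), bg$reaction_ids)
  stopifnot(length(rs) == n)
  rs <- as.integer(rs[bg$reaction_ids])

  # invert: metabolite -> producing / consuming reaction indices
  producers <- inverted_index(bg$produced)
  consumers <- inverted_index(bg$consumed)

  adj <- matrix(0, n, n, dimnames = list(bg$reaction_ids, bg$reaction_ids))
  chunks <- min(max(1L, as.integer(chunks)), n)
  bounds <- split(seq_len(n), ceiling(seq_len(n) / ceiling(n / chunks)))
  for (block in bounds) {
    for (i in block) {
      # reactions consuming something i produces, or producing something i consumes
      partners <- unique(c(unlist(consumers[bg$produced[[i]]], use.names = FALSE),
                           unlist(producers[bg$consumed[[i]]], use.names = FALSE)))
      partners <- partners[partners != i]      # no self-loops
      if (!length(partners)) next
      w <- if (weighted) {
        s <- rs[i] + rs[partners]
        ifelse(s > 0, 1 / s, 1.0)
      } else rep(1.0, length(partners))
      adj[i, partners] <- w
      adj[partners, i] <- w
    }
  }
  structure(list(adjacency = adj, reaction_ids = bg$reaction_ids,
                 rs = stats::setNames(rs, bg$reaction_ids), weighted = weighted),
            class = "reaction_graph")
}

inverted_index <- function(sets) {
  lens <- lengths(sets)
  idx <- rep(seq_along(sets), lens)
  split(idx, unlist(sets, use.names = FALSE))
}

#' @export
print.reaction_graph <- function(x, ...) {
  n_edges <- sum(x$adjacency > 0) / 2
  cat("Reaction-centric graph: ", length(x$reaction_ids), " reactions, ",
      n_edges, if (x$weighted) " weighted" else " unit-distance",
      " edges\n", sep = "")
  invisible(x)
}

#' Convert a reaction graph to igraph
#'
#' @param rg a \code{reaction_graph}.
#' @param nodes optional subset of reaction ids (induced subgraph).
#' @return an undirected igraph with edge attribute \code{weight} = the
#'   edge distance.
#' @export
reaction_igraph <- function(rg, nodes = NULL) {
  adj <- rg$adjacency
  if (!is.null(nodes)) adj <- adj[nodes, nodes, drop = FALSE]
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", weighted = TRUE)
}

#' Export graphs for Cytoscape
#'
#' GraphML via igraph, or simple interaction format (SIF); the reaction
#' graph can also be written as a 3-column weighted edge-list TSV.
#'
#' @param graph an igraph (see [reaction_igraph()], [bipartite_igraph()]).
#' @param path output file.
#' @param format \code{"graphml"}, \code{"sif"}, or \code{"edgelist"}.
#' @return \code{path}, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "sif", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph)
    if (format == "sif") {
      writeLines(paste(el[, 1], "rr", el[, 2]), path)
    } else {
      w <- if ("weight" %in% igraph::edge_attr_names(graph)) {
        igraph::E(graph)$weight
      } else rep(1, nrow(el))
      utils::write.table(
        data.frame(source = el[, 1], target = el[, 2], distance = w),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}
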
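#' Random connected subgraph by stochastic growth
#'
#' Implements the growth procedure verbatim: pick a seed reaction node at
#' random; pick a random edge from it and absorb the neighbor; then
#' repeatedly pick a node uniformly from the current sub-network and a
#' uniform random incident edge in a private working copy of the edge
#' structure -- if the far endpoint is already in the sub-network that edge
#' is deleted from the working copy, otherwise the endpoint is absorbed --
#' until the sub-network reaches the requested size.  If the seed's
#' available edges are exhausted below the requested size (the seed sits in
#' a too-small component), growth restarts from a fresh seed and a fresh
#' working copy.  The source graph itself is never mutated, so successive
#' draws are identically distributed.
#'
#' Note the procedure is the stated sampling scheme, not a uniform sampler
#' over connected subgraphs.
#'
#' @param rg a \code{reaction_graph} with at least one component of
#'   \code{size} nodes.
#' @param size number of reaction nodes to sample.
#' @param index optional precomputed [sampler_index()] (repeated draws on
#'   the same graph are much cheaper with one).
#' @return character vector of \code{size} reaction ids inducing a
#'   connected subgraph.  Uses R's RNG; seed with [set.seed()] for
#'   reproducibility.
#' @export
random_connected_subgraph <- function(rg, size, index = sampler_index(rg)) {
  n <- length(rg$reaction_ids)
  stopifnot(size >= 1, size <= n)
  adj0 <- index$adj
  if (index$max_component < size) {
    stop("no connected component has ", size, " nodes (largest: ",
         index$max_component, ")")
  }
  repeat {
    adj <- adj0                       # fresh private working copy per attempt
    sub <- sample.int(n, 1)
    if (size == 1) return(rg$reaction_ids[sub])
    ok <- TRUE
    while (length(sub) < size) {
      # nodes of the sub-network that still have edges in the working copy
      live <- sub[lengths(adj[sub]) > 0]
      if (!length(live)) { ok <- FALSE; break }   # component exhausted: restart
      v <- if (length(live) == 1) live else live[sample.int(length(live), 1)]
      nb <- adj[[v]]
      u <- if (length(nb) == 1) nb else nb[sample.int(length(nb), 1)]
      if (u %in% sub) {
        adj[[v]] <- setdiff(adj[[v]], u)          # delete the edge, both stubs
        adj[[u]] <- setdiff(adj[[u]], v)
      } else {
        sub <- c(sub, u)
      }
    }
    if (ok) return(rg$reaction_ids[sub])
  }
}

#' Precomputed index for repeated subgraph sampling
#'
#' Adjacency list plus the largest component size; pass to
#' [random_connected_subgraph()] to avoid recomputing them on every draw.
#'
#' @param rg a \code{reaction_graph}.
#' @return list with \code{adj} (integer adjacency list) and
#'   \code{max_component}.
#' @export
sampler_index <- function(rg) {
  n <- length(rg$reaction_ids)
  has_edge <- rg$adjacency > 0
  adj <- lapply(seq_len(n), function(i) which(has_edge[i, ]))
  list(adj = adj, max_component = max(lengths(graph_components(rg))))
}

#' SSM-frequency null distribution over random connected subgraphs
#'
#' Draws \code{n_samples} random connected subgraphs of the stated size and
#' counts, for each, the distinct SSM nodes produced or consumed by the
#' sampled reactions (the same counting rule as [annotate_tree()]).
#'
#' @param rg a \code{reaction_graph}.
#' @param model the underlying \code{metabolic_model}.
#' @param ssm_nodes character vector of SSM node ids.
#' @param size subgraph size (number of reactions).
#' @param n_samples number of draws.
#' @return a \code{null_distribution}: list with \code{size},
#'   \code{n_samples}, \code{ssm_counts} (integer vector),
#'   \code{ssm_density} (counts / size), \code{mean}, \code{sd}.
#' @export
ssm_frequency_distribution <- function(rg, model, ssm_nodes, size, n_samples,
                                       index = sampler_index(rg)) {
  touched <- reaction_ssm_sets(model, ssm_nodes)
  counts <- vapply(seq_len(n_samples), function(k) {
    nodes <- random_connected_subgraph(rg, size, index = index)
    length(unique(unlist(touched[nodes], use.names = FALSE)))
  }, 0L)
  structure(list(size = size, n_samples = n_samples, ssm_counts = counts,
                 ssm_density = counts / size,
                 mean = mean(counts), sd = stats::sd(counts)),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("SSM-frequency null: ", x$n_samples, " connected subgraphs of size ",
      x$size, "; mean ", format(x$mean, digits = 4), " +/- ",
      format(x$sd, digits = 4), " SSMs\n", sep = "")
  invisible(x)
}

#' Fraction of random subgraphs meeting the baseline density criterion
#'
#' For each subgraph size, repeatedly draws batches of random connected
#' subgraphs and reports the mean and standard deviation (across batches)
#' of the fraction whose SSM density exceeds 0.5 -- the background rate at
#' which the baseline module criterion fires by chance.
#'
#' @inheritParams ssm_frequency_distribution
#' @param sizes integer vector of subgraph sizes (default 2:10).
#' @param n_samples draws per batch.
#' @param repeats number of batches per size (default 10).
#' @return data.frame with columns \code{size}, \code{fraction},
#'   \code{sd}.
#' @export
baseline_fraction_by_size <- function(rg, model, ssm_nodes, sizes = 2:10,
                                      n_samples = 1000, repeats = 10) {
  index <- sampler_index(rg)
  rows <- lapply(sizes, function(sz) {
    fr <- vapply(seq_len(repeats), function(b) {
      null <- ssm_frequency_distribution(rg, model, ssm_nodes, sz, n_samples,
                                         index = index)
      mean(null$ssm_density > 0.5)
    }, 0)
    data.frame(size = sz, fraction = mean(fr), sd = stats::sd(fr))
  })
  do.call(rbind, rows)
}

#' Empirical module probability against a size-matched null
#'
#' The chance that a random connected subgraph of the same size has at
#' least as many SSMs as the module, estimated from the null draws with
#' the \code{(r + 1) / (n + 1)} pseudocount convention (capped at 1), so a
#' module beating every draw gets \code{1/(n+1)} rather than an impossible
#' zero.
#'
#' @param module a module record from an annotated \code{module_tree}
#'   (needs \code{size} and \code{ssm_count}).
#' @param null a \code{null_distribution} computed at the module's size on
#'   the same graph and SSM assignment.
#' @return probability in (0, 1].
#' @export
module_probability <- function(module, null) {
  if (is.null(module$ssm_count)) stop("module lacks ssm_count; annotate the tree first")
  if (module$size != null$size) {
    stop("null distribution size (", null$size,
         ") does not match module size (", module$size, ")")
  }
  r <- sum(null$ssm_counts >= module$ssm_count)
  min(1, (r + 1) / (null$n_samples + 1))
}

#' Attach empirical probabilities to an annotated tree
#'
#' Computes one null distribution per distinct module size in \code{sizes}
#' and fills \code{probability} for every module of those sizes.
#'
#' @param tree an annotated \code{module_tree}.
#' @inheritParams ssm_frequency_distribution
#' @param sizes module sizes to cover (default: all sizes <= 10 present in
#'   the tree, the range where random subgraph nulls are meaningful).
#' @return the tree with \code{probability} filled where covered.
#' @export
attach_module_probabilities <- function(rg, tree, model, ssm_nodes,
                                        sizes = NULL, n_samples = 1000) {
  mod_sizes <- vapply(tree$modules, `[[`, 0L, "size")
  if (is.null(sizes)) sizes <- sort(unique(mod_sizes[mod_sizes <= 10]))
  index <- sampler_index(rg)
  sizes <- sizes[sizes <= index$max_component]
  for (sz in sizes) {
    null <- ssm_frequency_distribution(rg, model, ssm_nodes, sz, n_samples,
                                       index = index)
    for (id in which(mod_sizes == sz)) {
      tree$modules[[id]]$probability <- module_probability(tree$modules[[id]], null)
    }
  }
  tree
}

#' Write a null distribution (with sidecar metadata)
#'
#' TSV of per-sample counts plus a JSON sidecar recording size, sample
#' count and summary statistics.
#'
#' @param null a \code{null_distribution}.
#' @param path output TSV; the sidecar is \code{<path>.json}.
#' @param seed the seed used (recorded in the sidecar; NA if unknown).
#' @return \code{path}, invisibly.
#' @export
write_null_distribution <- function(null, path, seed = NA) {
  utils::write.table(
    data.frame(size = null$size, sample_index = seq_len(null$n_samples),
               ssm_count = null$ssm_counts),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, size = null$size, n_samples = null$n_samples,
         mean = null$mean, sd = null$sd),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
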
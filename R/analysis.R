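#' Load a metabolite-to-pathway annotation table
#'
#' Two-column TSV with header (\code{metabolite_base_name},
#' \code{pathway}), many-to-many -- the shape of a KEGG pathway-membership
#' export.  Annotation is a static user-supplied file, not a live query.
#'
#' @param path TSV path.
#' @return named list: base name -> character vector of pathway names.
#' @export
load_pathway_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  if (ncol(df) < 2) stop("annotation TSV needs 2 columns (metabolite, pathway)")
  lapply(split(df[[2]], df[[1]]), unique)
}

#' Pathway-enrichment comparison for one module
#'
#' Collapses the module's SSM nodes to unique base names (the same
#' metabolite in several compartments counts once here -- unlike SSM
#' density, which counts model nodes), counts how many of those names each
#' annotated pathway covers, and takes the maximum.  When even the best
#' pathway covers fewer names than the module holds, the module's
#' interaction spans canonical pathways and is flagged counter-intuitive:
#' it could not have been read off a pathway map.
#'
#' @param module a module record from an annotated \code{module_tree}.
#' @param model the \code{metabolic_model}.
#' @param ssm_nodes character vector of SSM node ids.
#' @param annotation result of [load_pathway_annotation()] (an SSM with no
#'   annotation entry contributes to the module's count but to no pathway).
#' @return list with \code{module_id}, \code{n_unique_ssms},
#'   \code{max_pathway_count}, \code{best_pathways},
#'   \code{counter_intuitive}.
#' @export
pathway_enrichment <- function(module, model, ssm_nodes, annotation) {
  touched <- reaction_ssm_sets(model, ssm_nodes)
  nodes <- unique(unlist(touched[module$reaction_ids], use.names = FALSE))
  mets <- model$metabolites
  bases <- unique(mets$base_name[match(nodes, mets$node_id)])
  counts <- integer(0)
  annotated <- intersect(bases, names(annotation))
  if (length(annotated)) {
    counts <- table(unlist(annotation[annotated], use.names = FALSE))
  }
  max_count <- if (length(counts)) max(counts) else 0L
  best <- if (length(counts)) names(counts)[counts == max_count] else character(0)
  list(module_id = module$module_id,
       n_unique_ssms = length(bases),
       max_pathway_count = as.integer(max_count),
       best_pathways = best,
       counter_intuitive = max_count < length(bases))
}

#' Pathway enrichment for all baseline modules of a tree
#'
#' @param tree an annotated \code{module_tree}.
#' @inheritParams pathway_enrichment
#' @return data.frame with one row per baseline module (best pathways
#'   semicolon-joined) and attribute \code{percent_counter_intuitive}.
#' @export
enrich_tree <- function(tree, model, ssm_nodes, annotation) {
  ids <- baseline_modules(tree)
  rows <- lapply(ids, function(id) {
    e <- pathway_enrichment(tree$modules[[id]], model, ssm_nodes, annotation)
    data.frame(module_id = e$module_id, n_unique_ssms = e$n_unique_ssms,
               max_pathway_count = e$max_pathway_count,
               best_pathways = paste(e$best_pathways, collapse = ";"),
               counter_intuitive = e$counter_intuitive,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(module_id = integer(), n_unique_ssms = integer(),
               max_pathway_count = integer(), best_pathways = character(),
               counter_intuitive = logical())
  attr(out, "percent_counter_intuitive") <-
    if (nrow(out)) 100 * mean(out$counter_intuitive) else NA_real_
  out
}

# deepest module of `tree` whose reaction set contains all of `reactions`;
# deepest = smallest height, ties by highest density then smallest size.
best_containing_module <- function(tree, reactions) {
  cand <- which(vapply(tree$modules, function(m) {
    all(reactions %in% m$reaction_ids)
  }, TRUE))
  if (!length(cand)) return(NA_integer_)
  h <- vapply(tree$modules[cand], `[[`, 0L, "height")
  d <- vapply(tree$modules[cand], `[[`, 0, "ssm_density")
  s <- vapply(tree$modules[cand], `[[`, 0L, "size")
  cand[order(h, -d, s)][1]
}

#' Cross-condition module conservation
#'
#' For each baseline module of a reference partition, finds in every other
#' partition the module containing \emph{all} of its reactions that sits
#' deepest in that hierarchy (shortest distance to a terminal module;
#' ties broken by highest SSM density, then smallest size).  Such a module
#' always exists -- at worst the component root -- but a containing module
#' near the root has thousands of reactions and a diluted density, so the
#' reference module only counts as conserved when the matched module's SSM
#' density also exceeds 0.5.  Raw densities are reported for all entries
#' (heatmap-ready); the threshold is applied only for the conserved flag.
#'
#' @param reference an annotated \code{module_tree} (condition X).
#' @param others named list of annotated \code{module_tree}s over the same
#'   reaction universe (an error names missing reactions otherwise).
#' @return a \code{conservation_matrix}: list with \code{density} (matrix,
#'   rows = reference baseline module ids, columns = conditions),
#'   \code{conserved} (logical matrix, density > 0.5), and
#'   \code{matched_module} (integer matrix of matched module ids).
#' @export
conservation <- function(reference, others) {
  if (is.null(names(others)) || any(!nzchar(names(others)))) {
    names(others) <- paste0("condition_", seq_along(others))
  }
  universe <- function(tree) {
    roots <- which(vapply(tree$modules, function(m) is.na(m$parent), TRUE))
    sort(unique(unlist(lapply(tree$modules[roots], `[[`, "reaction_ids"))))
  }
  ref_univ <- universe(reference)
  for (nm in names(others)) {
    miss <- setdiff(ref_univ, universe(others[[nm]]))
    if (length(miss)) {
      stop("partition '", nm, "' lacks reactions present in the reference: ",
           paste(utils::head(miss, 5), collapse = ", "))
    }
  }
  rows <- baseline_modules(reference)
  dens <- matrix(NA_real_, length(rows), length(others),
                 dimnames = list(rows, names(others)))
  match_id <- matrix(NA_integer_, length(rows), length(others),
                     dimnames = dimnames(dens))
  for (i in seq_along(rows)) {
    reactions <- reference$modules[[rows[i]]]$reaction_ids
    for (j in seq_along(others)) {
      hit <- best_containing_module(others[[j]], reactions)
      match_id[i, j] <- hit
      dens[i, j] <- others[[j]]$modules[[hit]]$ssm_density
    }
  }
  structure(list(density = dens, conserved = dens > 0.5,
                 matched_module = match_id),
            class = "conservation_matrix")
}

#' @export
print.conservation_matrix <- function(x, ...) {
  cat("Conservation of ", nrow(x$density), " baseline modules across ",
      ncol(x$density), " partition(s); conserved entries: ",
      sum(x$conserved), "/", length(x$conserved), "\n", sep = "")
  invisible(x)
}

#' Write a conservation matrix as CSV
#'
#' Rows are reference module ids, columns condition names, entries the
#' best containing-module SSM densities (heatmap-ready).
#'
#' @param cm a \code{conservation_matrix}.
#' @param path output CSV.
#' @return \code{path}, invisibly.
#' @export
write_conservation_csv <- function(cm, path) {
  utils::write.csv(as.data.frame(cm$density), path, row.names = TRUE)
  invisible(path)
}

#' Compare weighted and unweighted partitions
#'
#' For each baseline module of the weighted (SSM-distance) partition,
#' reports the best corresponding module in the unweighted partition (the
#' containment search of [conservation()]) and whether that match itself
#' meets the baseline criteria; and counts, in each tree, the baseline
#' modules that capture the shared production \emph{and} consumption of
#' each listed cofactor (at least one module reaction produces it and at
#' least one consumes it, any compartment, reversible reactions counting
#' as both).
#'
#' @param weighted_tree,unweighted_tree annotated \code{module_tree}s over
#'   the same reaction set.
#' @param model the \code{metabolic_model}.
#' @param cofactors character vector of cofactor base names (default ATP,
#'   NADH, NADPH, FADH2; matching is case-insensitive on base names,
#'   compartments pooled).
#' @return list with \code{correspondence} (data.frame: weighted module
#'   id, its density, matched unweighted module id/density/baseline flag),
#'   \code{n_baseline_weighted}, \code{n_corresponding} (matches meeting
#'   baseline criteria), and \code{cofactor_counts} (data.frame: cofactor,
#'   weighted count, unweighted count).
#' @export
weighted_vs_unweighted_comparison <- function(weighted_tree, unweighted_tree,
                                              model,
                                              cofactors = c("atp", "nadh",
                                                            "nadph", "fadh2")) {
  rows <- baseline_modules(weighted_tree)
  corr <- do.call(rbind, lapply(rows, function(id) {
    m <- weighted_tree$modules[[id]]
    hit <- best_containing_module(unweighted_tree, m$reaction_ids)
    u <- unweighted_tree$modules[[hit]]
    data.frame(module_id = id, ssm_density = m$ssm_density,
               unweighted_module = hit, unweighted_density = u$ssm_density,
               unweighted_baseline = isTRUE(u$baseline))
  }))
  if (is.null(corr)) {
    corr <- data.frame(module_id = integer(), ssm_density = numeric(),
                       unweighted_module = integer(),
                       unweighted_density = numeric(),
                       unweighted_baseline = logical())
  }
  counts <- data.frame(
    cofactor = cofactors,
    weighted = vapply(cofactors, function(cf)
      count_cofactor_modules(weighted_tree, model, cf), 0L),
    unweighted = vapply(cofactors, function(cf)
      count_cofactor_modules(unweighted_tree, model, cf), 0L),
    row.names = NULL
  )
  list(correspondence = corr,
       n_baseline_weighted = length(rows),
       n_corresponding = sum(corr$unweighted_baseline),
       cofactor_counts = counts)
}

#' Count baseline modules coupled through a cofactor
#'
#' A module "involves the shared production/consumption" of a cofactor
#' when, within the module, at least one reaction produces it and at least
#' one consumes it (any compartmental version; a reversible reaction
#' counts on both sides).
#'
#' @param tree an annotated \code{module_tree}.
#' @param model the \code{metabolic_model}.
#' @param cofactor base name, matched case-insensitively.
#' @return integer count of baseline modules.
#' @export
count_cofactor_modules <- function(tree, model, cofactor) {
  mets <- model$metabolites
  cf_nodes <- mets$node_id[tolower(mets$base_name) == tolower(cofactor) &
                             !mets$excluded]
  if (!length(cf_nodes)) return(0L)
  rids <- vapply(model$reactions, `[[`, "", "id")
  produces <- vapply(model$reactions, function(r) {
    any(cf_nodes %in% names(r$products)) ||
      (r$reversible && any(cf_nodes %in% names(r$reactants)))
  }, TRUE)
  consumes <- vapply(model$reactions, function(r) {
    any(cf_nodes %in% names(r$reactants)) ||
      (r$reversible && any(cf_nodes %in% names(r$products)))
  }, TRUE)
  names(produces) <- names(consumes) <- rids
  sum(vapply(baseline_modules(tree), function(id) {
    rx <- tree$modules[[id]]$reaction_ids
    any(produces[rx]) && any(consumes[rx])
  }, TRUE))
}
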
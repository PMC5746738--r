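#' Canonical five-reaction toy fixture
#'
#' A fixed 5-reaction, 9-metabolite model in which reaction R1 touches
#' exactly three SSM nodes and R2 exactly two, R1 and R2 share a
#' metabolite (so the weighted edge between them is 1/(3+2) = 0.2), and a
#' chain of three score-zero reactions hangs off R2.  The wiring beyond
#' those constraints is this package's own reconstruction and is frozen
#' here as the canonical small fixture.
#'
#' @return list with \code{model} (a \code{metabolic_model}) and
#'   \code{ssm_nodes} (character vector).
#' @export
toy_network <- function() {
  bases <- c("s1", "s2", "s3", "s4", "s5", "x", "y", "z", "w")
  mets <- data.frame(node_id = paste0(bases, "[c]"), base_name = bases,
                     compartment = "c", excluded = FALSE,
                     stringsAsFactors = FALSE)
  rx <- function(id, reactants, products) {
    qualify <- function(b) if (length(b)) paste0(b, "[c]") else character(0)
    list(id = id, reversible = FALSE,
         reactants = stats::setNames(rep(1, length(reactants)), qualify(reactants)),
         products = stats::setNames(rep(1, length(products)), qualify(products)),
         ec_number = NA_character_)
  }
  model <- new_metabolic_model(
    name = "toy", compartments = "c", metabolites = mets,
    reactions = list(
      rx("R1", "s1", c("s2", "s3", "x")),
      rx("R2", c("x", "s4"), c("s5", "y")),
      rx("R3", "y", "z"),
      rx("R4", "z", "w"),
      rx("R5", "w", character(0))
    )
  )
  list(model = validate_model(model),
       ssm_nodes = paste0(c("s1", "s2", "s3", "s4", "s5"), "[c]"))
}

#' Synthetic-data generation settings
#'
#' Bundles the knobs of the synthetic generators.  The defaults are the
#' package's standing study conditions: two timepoints (\code{0h},
#' \code{3h}), five technical replicates with log-normal multiplicative
#' noise (sigma 0.2 on the log scale), an eight-fold shift at \code{3h}
#' for the designated significant metabolites, and two planted SSM-dense
#' reaction modules plus one NADPH-coupled reaction pair embedded in a
#' random background web.  See the methods vignette for the reasoning
#' behind each value.
#'
#' @param n_reactions total reactions, planted structure included.
#' @param n_metabolites background pool metabolite count (base names).
#' @param n_compartments number of compartments (some pool metabolites get
#'   a second compartmental node when > 1).
#' @param currency_fraction fraction of the pool that is currency
#'   (high-degree, named so the default exclusion list catches them).
#' @param planted_modules list of \code{list(n_reactions, n_ssm)} records:
#'   disjoint reaction sets sharing \code{n_ssm} designated SSMs each.
#' @param cofactor_pair logical; plant the two-reaction NADPH-coupled pair
#'   used to probe the weighted-vs-unweighted contrast.
#' @param sigma log-normal replicate noise (log scale).
#' @param effect multiplicative shift at \code{t1} for planted SSMs.
#' @param n_replicates technical replicates per timepoint.
#' @param seed RNG seed; every generator is a pure function of the spec.
#' @return a \code{synthetic_spec} list.
#' @export
synthetic_spec <- function(n_reactions = 50, n_metabolites = 40,
                           n_compartments = 2, currency_fraction = 0.1,
                           planted_modules = list(list(n_reactions = 5, n_ssm = 6),
                                                  list(n_reactions = 4, n_ssm = 5)),
                           cofactor_pair = TRUE,
                           sigma = 0.2, effect = 8, n_replicates = 5,
                           seed = 1) {
  spec <- list(n_reactions = n_reactions, n_metabolites = n_metabolites,
               n_compartments = n_compartments,
               currency_fraction = currency_fraction,
               planted_modules = planted_modules,
               cofactor_pair = cofactor_pair,
               sigma = sigma, effect = effect,
               n_replicates = n_replicates, seed = seed)
  n_planted <- sum(vapply(planted_modules, `[[`, 0, "n_reactions")) +
    if (cofactor_pair) 2L else 0L
  if (n_planted >= n_reactions) {
    stop("planted structure (", n_planted, " reactions) does not fit in n_reactions = ",
         n_reactions)
  }
  stopifnot(n_reactions > 0, n_metabolites > 0, n_compartments >= 1,
            currency_fraction >= 0, currency_fraction < 1,
            sigma > 0, effect > 0, n_replicates >= 1)
  structure(spec, class = "synthetic_spec")
}

# currency base names; the first few match the default exclusion list so
# synthetic models exercise the exclusion policy end to end
currency_names <- function(k) {
  pool <- c("h", "h2o", "pi", "co2", "o2")
  if (k <= length(pool)) pool[seq_len(k)] else c(pool, paste0("cur", seq_len(k - length(pool))))
}

#' Random metabolic model
#'
#' A connected random background web: reactions are chained through
#' dedicated link metabolites (reaction i produces the reactant of
#' reaction i + 1) and additionally draw 2--4 substrates/products from a
#' metabolite pool; currency metabolites are attached broadly so they
#' become high-degree hubs.  Pure function of the spec (fixed seed gives a
#' byte-identical model).
#'
#' @param spec a \code{synthetic_spec} (planted fields are ignored here;
#'   see [plant_and_measure()] for planted structure).
#' @return a \code{metabolic_model}.
#' @export
random_model <- function(spec = synthetic_spec()) {
  withr::with_seed(spec$seed, build_random_model(spec))
}

build_random_model <- function(spec, n_reactions = spec$n_reactions,
                               id_prefix = "bg") {
  comps <- c("c", "m", "e", "n", "r", "x", "l", "g")[seq_len(spec$n_compartments)]
  n_cur <- floor(spec$currency_fraction * spec$n_metabolites)
  cur <- currency_names(n_cur)
  pool <- sprintf("met%03d", seq_len(spec$n_metabolites - n_cur))
  link <- sprintf("link%03d", seq_len(n_reactions))

  base_comp <- function(bases, comp) {
    data.frame(node_id = paste0(bases, "[", comp, "]"), base_name = bases,
               compartment = comp, excluded = FALSE, stringsAsFactors = FALSE)
  }
  mets <- base_comp(c(pool, cur, link), "c")
  if (spec$n_compartments > 1 && length(pool)) {
    second <- pool[stats::runif(length(pool)) < 0.25]
    if (length(second)) mets <- rbind(mets, base_comp(second, comps[2]))
  }
  pool_nodes <- mets$node_id[mets$base_name %in% pool]
  cur_nodes <- mets$node_id[mets$base_name %in% cur]

  reactions <- lapply(seq_len(n_reactions), function(i) {
    k_in <- sample(1:2, 1); k_out <- sample(1:2, 1)
    extra_in <- sample(pool_nodes, k_in)
    extra_out <- sample(setdiff(pool_nodes, extra_in), k_out)
    reac <- c(paste0(link[i], "[c]"), extra_in)
    prod <- c(paste0(link[if (i < n_reactions) i + 1 else 1], "[c]"), extra_out)
    if (length(cur_nodes) >= 2 && stats::runif(1) < 0.5) {
      pair <- sample(cur_nodes, 2)
      reac <- c(reac, pair[1])
      prod <- c(prod, pair[2])
    }
    list(id = sprintf("%s%03d", id_prefix, i),
         reversible = stats::runif(1) < 0.3,
         reactants = stats::setNames(rep(1, length(reac)), reac),
         products = stats::setNames(rep(1, length(prod)), prod),
         ec_number = NA_character_)
  })
  validate_model(new_metabolic_model(
    name = paste0("synthetic_", spec$seed), compartments = comps,
    metabolites = mets, reactions = reactions))
}

#' Generate a model with planted SSM-dense modules plus measurements
#'
#' Builds a random background web ([random_model()] wiring), embeds the
#' planted modules and the optional NADPH-coupled pair, and simulates a
#' replicate metabolomics dataset in which the designated SSM metabolites
#' shift \code{effect}-fold between \code{0h} and \code{3h} (half
#' accumulate, half deplete) under log-normal replicate noise.
#'
#' Each planted module is a chain of reactions coupled through internal
#' link metabolites, every reaction also producing/consuming three of the
#' module's designated SSM metabolites, so intra-module edges are dense
#' and short once weighted.  The NADPH pair is two reactions coupled only
#' through NADPH (an SSM) plus one SSM product each; each member also has
#' a unit-distance tether into a different region of the background, so
#' with unit edge distances nothing distinguishes the pair from its
#' branches -- the contrast the edge-weighting is designed to win.
#'
#' @param spec a \code{synthetic_spec}.
#' @return list with \code{model}, \code{dataset} (long-format
#'   data.frame), \code{compartment_map}, \code{timepoints}
#'   (\code{c("0h","3h")}), and \code{truth}: \code{ssm_bases},
#'   \code{modules} (list of planted reaction-id vectors),
#'   \code{cofactor_pair} (reaction ids, or NULL).
#' @export
plant_and_measure <- function(spec = synthetic_spec()) {
  withr::with_seed(spec$seed, {
    n_pl <- sum(vapply(spec$planted_modules, `[[`, 0, "n_reactions")) +
      if (spec$cofactor_pair) 2L else 0L
    model <- build_random_model(spec, n_reactions = spec$n_reactions - n_pl)
    n_bg <- length(model$reactions)

    add_mets <- function(bases, comp = "c") {
      model$metabolites <<- rbind(
        model$metabolites,
        data.frame(node_id = paste0(bases, "[", comp, "]"), base_name = bases,
                   compartment = comp, excluded = FALSE, stringsAsFactors = FALSE))
    }
    add_rx <- function(id, reactants, products, reversible = FALSE) {
      model$reactions[[length(model$reactions) + 1L]] <<-
        list(id = id, reversible = reversible,
             reactants = stats::setNames(rep(1, length(reactants)), reactants),
             products = stats::setNames(rep(1, length(products)), products),
             ec_number = NA_character_)
    }

    ssm_bases <- character(0)
    truth_modules <- list()
    for (k in seq_along(spec$planted_modules)) {
      pm <- spec$planted_modules[[k]]
      ssm_k <- sprintf("pssm%d_%d", k, seq_len(pm$n_ssm))
      chain_k <- sprintf("plink%d_%d", k, seq_len(pm$n_reactions + 1))
      add_mets(c(ssm_k, chain_k))
      ids <- sprintf("pl%d_%02d", k, seq_len(pm$n_reactions))
      for (i in seq_len(pm$n_reactions)) {
        pick <- function(off) ssm_k[(i + off - 1) %% pm$n_ssm + 1]
        add_rx(ids[i],
               reactants = paste0(c(chain_k[i], pick(0)), "[c]"),
               products = paste0(c(chain_k[i + 1], pick(1), pick(2)), "[c]"))
      }
      # hang the module off the background through its first chain metabolite
      anchor <- sample(n_bg, 1)
      r <- model$reactions[[anchor]]
      r$products <- c(r$products, stats::setNames(1, paste0(chain_k[1], "[c]")))
      model$reactions[[anchor]] <- r
      ssm_bases <- c(ssm_bases, ssm_k)
      truth_modules[[k]] <- ids
    }

    cof_pair <- NULL
    if (spec$cofactor_pair) {
      add_mets(c("nadph", "nadp", "cfa", "cfb", "cfa_pre", "cfb_pre"))
      bg_link <- function(i) paste0(sprintf("link%03d", i), "[c]")
      t1 <- sample(n_bg, 1)
      t2 <- sample(setdiff(seq_len(n_bg), t1), 1)
      # CP1: cfa_pre + nadp -> cfa + nadph, tethered to background region 1
      add_rx("cp1", reactants = c("cfa_pre[c]", "nadp[c]", bg_link(t1)),
             products = c("cfa[c]", "nadph[c]"))
      # CP2: cfb_pre + nadph -> cfb + nadp, tethered to background region 2
      add_rx("cp2", reactants = c("cfb_pre[c]", "nadph[c]"),
             products = c("cfb[c]", "nadp[c]", bg_link(t2)))
      ssm_bases <- c(ssm_bases, "nadph", "cfa", "cfb")
      cof_pair <- c("cp1", "cp2")
    }
    model <- validate_model(model)

    measured <- unique(model$metabolites$base_name)
    measured <- setdiff(measured, currency_names(1000))   # extract skips inorganics
    dirs <- stats::setNames(rep_len(c(1, -1), length(ssm_bases)), ssm_bases)
    rows <- lapply(measured, function(met) {
      mu <- stats::rlnorm(1, log(1e6), 1)
      do.call(rbind, lapply(c("0h", "3h"), function(tp) {
        shift <- if (tp == "3h" && met %in% ssm_bases) spec$effect^dirs[met] else 1
        data.frame(base_name = met, timepoint = tp,
                   replicate = seq_len(spec$n_replicates),
                   peak_area = mu * shift *
                     stats::rlnorm(spec$n_replicates, 0, spec$sigma),
                   stringsAsFactors = FALSE)
      }))
    })
    dataset <- do.call(rbind, rows)

    cmap <- lapply(split(model$metabolites$node_id, model$metabolites$base_name),
                   unique)
    list(model = model, dataset = dataset, compartment_map = cmap,
         timepoints = c("0h", "3h"),
         truth = list(ssm_bases = ssm_bases, modules = truth_modules,
                      cofactor_pair = cof_pair))
  })
}

#' Was a planted reaction set recovered as a baseline module?
#'
#' TRUE when some baseline-criteria module of the annotated tree contains
#' every one of the planted reactions.
#'
#' @param tree an annotated \code{module_tree}.
#' @param reactions character vector of reaction ids.
#' @return logical.
#' @export
module_recovered <- function(tree, reactions) {
  any(vapply(baseline_modules(tree), function(id) {
    all(reactions %in% tree$modules[[id]]$reaction_ids)
  }, TRUE))
}

#' Run the full pipeline on one synthetic replicate
#'
#' Convenience wrapper used by tests and the acceptance workflow:
#' generates a planted replicate, applies the default exclusions, calls
#' SSMs (exact rank-sum test, alpha 0.05), expands them to model nodes,
#' builds the weighted (and optionally unweighted) reaction graph,
#' partitions it and annotates the tree.
#'
#' @param spec a \code{synthetic_spec}.
#' @param alpha SSM significance threshold.
#' @param unweighted also run the unit-distance partition.
#' @return list with \code{truth}, \code{ssm_node_ids}, \code{tree}
#'   (weighted) and \code{tree_unweighted} (or NULL).
#' @export
run_synthetic_pipeline <- function(spec = synthetic_spec(), alpha = 0.05,
                                   unweighted = FALSE) {
  sim <- plant_and_measure(spec)
  model <- suppressWarnings(apply_exclusions(sim$model))
  ssm <- suppressWarnings(
    call_ssms(sim$dataset, t0 = sim$timepoints[1], t1 = sim$timepoints[2],
              alpha = alpha, method = "auto"))
  ssm <- suppressWarnings(expand_to_model(ssm, sim$compartment_map, model))
  nodes <- ssm_nodes(ssm)
  bg <- build_bipartite(model)
  rs <- reaction_scores(model, nodes)
  rg <- build_reaction_graph(bg, rs, weighted = TRUE)
  tree <- annotate_tree(recursive_partition(rg), model, nodes)
  tree_u <- NULL
  if (unweighted) {
    rg_u <- build_reaction_graph(bg, rs, weighted = FALSE)
    tree_u <- annotate_tree(recursive_partition(rg_u), model, nodes)
  }
  list(truth = sim$truth, ssm_node_ids = nodes, model = model,
       reaction_graph = rg, tree = tree, tree_unweighted = tree_u)
}
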
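# model with two compartmental copies of three SSMs feeding two reactions
enr_fixture <- function() {
  bases <- c("akg", "succ", "fum", "glc")
  mets <- do.call(rbind, lapply(c("c", "m"), function(cp) {
    data.frame(node_id = paste0(bases, "[", cp, "]"), base_name = bases,
               compartment = cp, excluded = FALSE, stringsAsFactors = FALSE)
  }))
  rxns <- list(
    list(id = "Ra", reversible = FALSE,
         reactants = c("akg[c]" = 1), products = c("succ[c]" = 1),
         ec_number = NA_character_),
    list(id = "Rb", reversible = FALSE,
         reactants = c("succ[m]" = 1), products = c("fum[m]" = 1),
         ec_number = NA_character_)
  )
  mma:::validate_model(mma:::new_metabolic_model("enr", c("c", "m"), mets, rxns))
}

test_that("enrichment collapses compartments and flags counter-intuition", {
  model <- enr_fixture()
  ssm <- c("akg[c]", "succ[c]", "succ[m]", "fum[m]")  # 4 nodes, 3 base names
  module <- list(module_id = 1L, reaction_ids = c("Ra", "Rb"))

  tca <- list(akg = "TCA cycle", succ = "TCA cycle", fum = "TCA cycle")
  e1 <- pathway_enrichment(module, model, ssm, tca)
  expect_equal(e1$n_unique_ssms, 3)        # compartments collapsed
  expect_equal(e1$max_pathway_count, 3)
  expect_equal(e1$best_pathways, "TCA cycle")
  expect_false(e1$counter_intuitive)

  partial <- list(akg = "TCA cycle", succ = "TCA cycle")
  e2 <- pathway_enrichment(module, model, ssm, partial)
  expect_equal(e2$max_pathway_count, 2)
  expect_true(e2$counter_intuitive)

  e3 <- pathway_enrichment(module, model, ssm, list())
  expect_equal(e3$max_pathway_count, 0)
  expect_true(e3$counter_intuitive)
})

test_that("counter-intuition is monotone in annotation coverage", {
  model <- enr_fixture()
  ssm <- c("akg[c]", "succ[m]", "fum[m]")
  module <- list(module_id = 1L, reaction_ids = c("Ra", "Rb"))
  anns <- list(
    list(),
    list(akg = "P"),
    list(akg = "P", succ = "P"),
    list(akg = "P", succ = "P", fum = "P")
  )
  flags <- vapply(anns, function(a) {
    pathway_enrichment(module, model, ssm, a)$counter_intuitive
  }, TRUE)
  expect_false(is.unsorted(rev(flags)))   # TRUE...TRUE FALSE...FALSE
  expect_false(flags[4])
})

test_that("annotation TSV loader builds a many-to-many lookup", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("metabolite_base_name\tpathway",
               "akg\tTCA cycle", "akg\tButanoate metabolism",
               "succ\tTCA cycle"), path)
  ann <- load_pathway_annotation(path)
  expect_setequal(ann$akg, c("TCA cycle", "Butanoate metabolism"))
  expect_equal(ann$succ, "TCA cycle")
})

test_that("a partition compared against itself conserves every baseline module", {
  res <- run_synthetic_pipeline(synthetic_spec(seed = 21))
  cm <- conservation(res$tree, list(self = res$tree))
  own <- vapply(baseline_modules(res$tree),
                function(id) res$tree$modules[[id]]$ssm_density, 0)
  expect_equal(unname(cm$density[, "self"]), own)
  expect_true(all(cm$conserved))
  expect_equal(unname(cm$matched_module[, "self"]), baseline_modules(res$tree))
})

test_that("scattering a module's reactions forces a near-root, diluted match", {
  res <- run_synthetic_pipeline(synthetic_spec(seed = 22))
  tree <- res$tree
  ref_ids <- baseline_modules(tree)
  # a fake comparison partition: one root holding everything, no structure
  all_rx <- sort(unique(unlist(lapply(
    tree$modules[vapply(tree$modules, function(m) is.na(m$parent), TRUE)],
    `[[`, "reaction_ids"))))
  flat <- structure(list(modules = list(list(
    module_id = 1L, parent = NA_integer_, children = integer(0),
    reaction_ids = all_rx, size = length(all_rx), q_split = NA_real_)),
    weighted = TRUE), class = "module_tree")
  flat <- annotate_tree(flat, res$model, res$ssm_node_ids)
  cm <- conservation(tree, list(flat = flat))
  root_density <- flat$modules[[1]]$ssm_density
  expect_true(all(cm$density[, "flat"] == root_density))
  # conservation entries always at least match the root-of-component density
  cm_self <- conservation(tree, list(self = tree))
  expect_true(all(cm_self$density[, "self"] >= root_density - 1e-12))
})

test_that("mismatched reaction universes are rejected by name", {
  res <- run_synthetic_pipeline(synthetic_spec(seed = 23))
  tree <- res$tree
  # drop one reaction from a copied tree's universe
  clipped <- tree
  root <- which(vapply(clipped$modules, function(m) is.na(m$parent), TRUE))[1]
  clipped$modules[[root]]$reaction_ids <-
    clipped$modules[[root]]$reaction_ids[-1]
  expect_error(conservation(tree, list(bad = clipped)), "lacks reactions")
})

test_that("weighted-vs-unweighted comparison reuses containment matching", {
  res <- run_synthetic_pipeline(synthetic_spec(seed = 24), unweighted = TRUE)
  cmp <- weighted_vs_unweighted_comparison(res$tree, res$tree, res$model)
  # identical trees: every baseline module corresponds at its own density
  expect_equal(cmp$n_corresponding, cmp$n_baseline_weighted)
  expect_equal(cmp$correspondence$unweighted_density,
               cmp$correspondence$ssm_density)
  expect_equal(cmp$cofactor_counts$weighted, cmp$cofactor_counts$unweighted)

  cmp2 <- weighted_vs_unweighted_comparison(res$tree, res$tree_unweighted,
                                            res$model)
  expect_lte(cmp2$n_corresponding, cmp2$n_baseline_weighted)
  expect_true(all(c("nadph", "atp") %in% cmp2$cofactor_counts$cofactor))
})

test_that("cofactor modules need shared production AND consumption", {
  mets <- data.frame(
    node_id = c("atp[c]", "a[c]", "b[c]", "s1[c]", "s2[c]"),
    base_name = c("atp", "a", "b", "s1", "s2"),
    compartment = "c", excluded = FALSE)
  # both reactions consume ATP; nothing produces it
  consume_only <- mma:::validate_model(mma:::new_metabolic_model(
    "co", "c", mets, list(
      list(id = "R1", reversible = FALSE,
           reactants = c("atp[c]" = 1, "s1[c]" = 1), products = c("a[c]" = 1),
           ec_number = NA_character_),
      list(id = "R2", reversible = FALSE,
           reactants = c("atp[c]" = 1, "a[c]" = 1),
           products = c("b[c]" = 1, "s2[c]" = 1),
           ec_number = NA_character_))))
  ssm <- c("s1[c]", "s2[c]")
  rg <- build_reaction_graph(build_bipartite(consume_only),
                             reaction_scores(consume_only, ssm))
  tree <- annotate_tree(recursive_partition(rg), consume_only, ssm)
  expect_equal(count_cofactor_modules(tree, consume_only, "atp"), 0L)

  # flip R1 to produce ATP: the pair now shares production and consumption
  produce <- consume_only
  produce$reactions[[1]]$reactants <- c("s1[c]" = 1)
  produce$reactions[[1]]$products <- c("a[c]" = 1, "atp[c]" = 1)
  rg2 <- build_reaction_graph(build_bipartite(produce),
                              reaction_scores(produce, ssm))
  tree2 <- annotate_tree(recursive_partition(rg2), produce, ssm)
  expect_equal(count_cofactor_modules(tree2, produce, "atp"), 1L)
})

test_that("per-condition counter-intuitive percentages aggregate like a survey", {
  # the cross-liver summary shape: per condition %, then mean and sd
  pcts <- vapply(c(31, 32, 33), function(s) {
    res <- run_synthetic_pipeline(synthetic_spec(seed = s))
    ann <- list()  # no annotation: every SSM-bearing module counts
    enr <- enrich_tree(res$tree, res$model, res$ssm_node_ids, ann)
    attr(enr, "percent_counter_intuitive")
  }, 0)
  expect_length(pcts, 3)
  expect_true(all(pcts >= 0 & pcts <= 100))
  expect_false(is.na(sd(pcts)))
})
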
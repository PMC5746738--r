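#' Read a metabolic model
#'
#' Loads a genome-scale metabolic model from either the package's canonical
#' JSON dialect or an SBML Level 3 file, and validates it.  A model carries
#' an ordered reaction list and an ordered metabolite table; all downstream
#' matrices (bipartite connectivity, reaction-centric adjacency) index by
#' this order, which is exactly the order of records in the source file and
#' therefore stable across runs.
#'
#' The JSON dialect is:
#' \preformatted{
#' {"name": ..., "compartments": [...],
#'  "metabolites": [{"id": "glyc[c]", "base_name": "glyc", "compartment": "c"}, ...],
#'  "reactions":  [{"id": "R1", "reversible": false,
#'                  "stoich": {"glyc[c]": -1, "dha[c]": 1}}, ...]}
#' }
#' Negative stoichiometric coefficients denote reactants, positive products.
#' Compartment-qualified identifiers use the bracket-suffix convention
#' \code{base[compartment]} common in genome-scale modelling.
#'
#' @param path path to the model file.
#' @param format \code{"json"} (default, the package dialect) or \code{"sbml"}.
#' @return a \code{metabolic_model}: a list with elements \code{name},
#'   \code{compartments}, \code{metabolites} (data.frame with columns
#'   \code{node_id}, \code{base_name}, \code{compartment}, \code{excluded})
#'   and \code{reactions} (list of records with \code{id}, \code{reversible},
#'   \code{reactants}, \code{products} -- named numeric vectors of positive
#'   coefficients -- and optional \code{ec_number}).
#' @seealso [write_model_json()], [apply_exclusions()], [load_compartment_map()]
#' @export
read_model <- function(path, format = c("json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  model <- switch(format,
    json = read_model_json(path),
    sbml = read_model_sbml(path)
  )
  validate_model(model)
}

read_model_json <- function(path) {
  raw <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("malformed JSON model '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  for (field in c("metabolites", "reactions")) {
    if (is.null(raw[[field]])) stop("model JSON missing '", field, "'")
  }
  mets <- data.frame(
    node_id     = vapply(raw$metabolites, function(m) as.character(m$id), ""),
    base_name   = vapply(raw$metabolites, function(m) as.character(m$base_name), ""),
    compartment = vapply(raw$metabolites, function(m) as.character(m$compartment), ""),
    excluded    = FALSE,
    stringsAsFactors = FALSE
  )
  reactions <- lapply(raw$reactions, function(r) {
    stoich <- unlist(r$stoich)
    if (is.null(stoich) || !length(stoich)) {
      stop("reaction '", r$id, "': empty stoichiometry")
    }
    if (anyDuplicated(names(r$stoich))) {
      stop("reaction '", r$id, "': duplicate stoichiometry keys")
    }
    list(
      id         = as.character(r$id),
      reversible = isTRUE(r$reversible),
      reactants  = -stoich[stoich < 0],
      products   = stoich[stoich > 0],
      ec_number  = if (!is.null(r$ec_number)) as.character(r$ec_number) else NA_character_
    )
  })
  compartments <- if (!is.null(raw$compartments)) {
    as.character(unlist(raw$compartments))
  } else {
    unique(mets$compartment)
  }
  new_metabolic_model(
    name = if (!is.null(raw$name)) as.character(raw$name) else "model",
    compartments = compartments, metabolites = mets, reactions = reactions
  )
}

# Minimal SBML Level 3 reader (species, compartments, reactions with
# listOfReactants/listOfProducts).  Species are mapped into the
# base[compartment] identifier convention using the species name attribute
# when present, else the species id.
read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  ns <- "*"  # namespace-agnostic: SBML levels differ in namespace URI
  model_node <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (is.na(model_node)) stop("SBML file has no <model> element: ", path)
  species <- xml2::xml_find_all(model_node, ".//*[local-name()='species']")
  if (!length(species)) stop("SBML model declares no species: ", path)
  sp_id   <- xml2::xml_attr(species, "id")
  sp_name <- xml2::xml_attr(species, "name")
  sp_comp <- xml2::xml_attr(species, "compartment")
  base <- ifelse(is.na(sp_name) | sp_name == "", sub("^M_", "", sp_id), sp_name)
  mets <- data.frame(
    node_id     = paste0(base, "[", sp_comp, "]"),
    base_name   = base,
    compartment = sp_comp,
    excluded    = FALSE,
    stringsAsFactors = FALSE
  )
  node_of <- stats::setNames(mets$node_id, sp_id)

  rxn_nodes <- xml2::xml_find_all(model_node, ".//*[local-name()='reaction']")
  side <- function(rxn, tag) {
    refs <- xml2::xml_find_all(
      rxn, paste0(".//*[local-name()='", tag, "']/*[local-name()='speciesReference']"))
    if (!length(refs)) return(stats::setNames(numeric(0), character(0)))
    ids <- xml2::xml_attr(refs, "species")
    coef <- suppressWarnings(as.numeric(xml2::xml_attr(refs, "stoichiometry")))
    coef[is.na(coef)] <- 1
    unknown <- setdiff(ids, names(node_of))
    if (length(unknown)) {
      stop("reaction '", xml2::xml_attr(rxn, "id"),
           "' references undeclared species: ", paste(unknown, collapse = ", "))
    }
    stats::setNames(coef, node_of[ids])
  }
  reactions <- lapply(rxn_nodes, function(rxn) {
    rev_attr <- xml2::xml_attr(rxn, "reversible")
    list(
      id         = xml2::xml_attr(rxn, "id"),
      reversible = identical(tolower(rev_attr), "true"),
      reactants  = side(rxn, "listOfReactants"),
      products   = side(rxn, "listOfProducts"),
      ec_number  = NA_character_
    )
  })
  comp_nodes <- xml2::xml_find_all(model_node, ".//*[local-name()='compartment']")
  compartments <- unique(c(xml2::xml_attr(comp_nodes, "id"), sp_comp))
  name <- xml2::xml_attr(model_node, "name")
  if (is.na(name)) name <- xml2::xml_attr(model_node, "id")
  if (is.na(name)) name <- basename(path)
  new_metabolic_model(name = name, compartments = compartments,
                      metabolites = mets, reactions = reactions)
}

new_metabolic_model <- function(name, compartments, metabolites, reactions) {
  structure(
    list(name = name, compartments = compartments,
         metabolites = metabolites, reactions = reactions),
    class = "metabolic_model"
  )
}

validate_model <- function(model) {
  mets <- model$metabolites
  if (anyDuplicated(mets$node_id)) {
    stop("duplicate metabolite node_id: ",
         paste(unique(mets$node_id[duplicated(mets$node_id)]), collapse = ", "))
  }
  key <- paste(mets$base_name, mets$compartment, sep = "\r")
  if (anyDuplicated(key)) {
    stop("(base_name, compartment) must identify a unique node_id")
  }
  rids <- vapply(model$reactions, `[[`, "", "id")
  if (anyDuplicated(rids)) {
    stop("duplicate reaction_id: ", paste(unique(rids[duplicated(rids)]), collapse = ", "))
  }
  for (r in model$reactions) {
    touched <- c(names(r$reactants), names(r$products))
    if (!length(touched)) stop("reaction '", r$id, "': reactants and products both empty")
    missing <- setdiff(touched, mets$node_id)
    if (length(missing)) {
      stop("reaction '", r$id, "' references undeclared metabolites: ",
           paste(missing, collapse = ", "))
    }
    if (any(c(r$reactants, r$products) <= 0)) {
      stop("reaction '", r$id, "': stoichiometric coefficients must be nonzero")
    }
  }
  model
}

#' Write a metabolic model to the package JSON dialect
#'
#' Inverse of [read_model()] with \code{format = "json"} up to field
#' ordering; the exclusion flag is not serialized (it is policy applied by
#' [apply_exclusions()], not part of the model).  The dialect stores one
#' signed coefficient per metabolite, so a species appearing on both sides
#' of a reaction is written as its net coefficient (with a warning).
#'
#' @param model a \code{metabolic_model}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    list(id = m$node_id, base_name = m$base_name, compartment = m$compartment)
  })
  rxns <- lapply(model$reactions, function(r) {
    stoich <- c(-r$reactants, r$products)
    if (anyDuplicated(names(stoich))) {
      # the signed-coefficient dialect stores one entry per metabolite, so a
      # species on both sides of a reaction is written as its net coefficient
      stoich <- vapply(split(stoich, names(stoich)), sum, 0)
      stoich <- stoich[stoich != 0]
      warning("reaction '", r$id, "': metabolite on both sides written as ",
              "net coefficient in the JSON dialect")
    }
    out <- list(id = r$id, reversible = r$reversible, stoich = as.list(stoich))
    if (!is.na(r$ec_number)) out$ec_number <- r$ec_number
    out
  })
  jsonlite::write_json(
    list(name = model$name, compartments = as.list(model$compartments),
         metabolites = mets, reactions = rxns),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model '", x$name, "': ",
      length(x$reactions), " reactions, ",
      nrow(x$metabolites), " metabolites (",
      sum(x$metabolites$excluded), " excluded), ",
      length(x$compartments), " compartments\n", sep = "")
  invisible(x)
}

#' Flag currency metabolites as excluded
#'
#' Metabolites whose production and consumption do not constitute a
#' meaningful interaction between reactions (protons, water, inorganic
#' ions, ...) are flagged so that they never contribute edges to the
#' bipartite or reaction-centric graphs.  Entries may be compartment-free
#' base names (all compartmental versions are flagged) or exact
#' compartment-qualified node ids.  Energy cofactors (ATP, NAD(P)H, FADH2)
#' are deliberately \emph{not} in the default list: their shared production
#' and consumption is the interaction this analysis is designed to surface.
#'
#' Idempotent; unknown names are ignored with a warning.
#'
#' @param model a \code{metabolic_model}.
#' @param exclusion_list character vector of base names or node ids, or a
#'   path to a plain-text list (one entry per line, \code{#} comments).
#'   Defaults to the list shipped with the package, a reconstruction of the
#'   usual currency/inorganic set.
#' @return the model with \code{metabolites$excluded} updated.
#' @export
apply_exclusions <- function(model, exclusion_list = default_exclusions()) {
  if (length(exclusion_list) == 1 && !is.null(exclusion_list) &&
      file.exists(exclusion_list)) {
    exclusion_list <- read_exclusion_file(exclusion_list)
  }
  exclusion_list <- unique(as.character(exclusion_list))
  if (!length(exclusion_list)) return(model)
  mets <- model$metabolites
  hit <- mets$base_name %in% exclusion_list | mets$node_id %in% exclusion_list
  matched <- exclusion_list %in% c(mets$base_name, mets$node_id)
  if (any(!matched)) {
    warning("exclusion entries not present in model (ignored): ",
            paste(exclusion_list[!matched], collapse = ", "))
  }
  model$metabolites$excluded <- mets$excluded | hit
  model
}

read_exclusion_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Default currency-metabolite exclusion list
#'
#' Compartment-free base names of ubiquitous inorganic species and water.
#' This is the package's own reconstruction of common practice; override it
#' by passing your own list to [apply_exclusions()].
#'
#' @return character vector of base names.
#' @export
default_exclusions <- function() {
  read_exclusion_file(system.file("extdata", "currency_metabolites.txt",
                                  package = "mma", mustWork = TRUE))
}

#' Load a measured-name to model-node compartment map
#'
#' Two-column TSV (header \code{measured_name}, \code{node_id}),
#' many-to-many: a measured base name maps to every compartmental version
#' of that metabolite in the model, so that one significant measurement
#' flags all of its compartmental nodes.
#'
#' @param path TSV path.
#' @param model optional \code{metabolic_model}; when given, mapped node ids
#'   absent from the model are collected in the \code{unmatched} attribute
#'   (and reported with a warning) rather than silently dropped.
#' @return named list mapping measured base name to a character vector of
#'   node ids, with attribute \code{unmatched} (data.frame of rows whose
#'   node_id is not in the model; empty if no model given).
#' @export
load_compartment_map <- function(path, model = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || (length(lines) == 1 && !nzchar(trimws(lines)))) {
    out <- list()
    attr(out, "unmatched") <- data.frame(measured_name = character(),
                                         node_id = character())
    return(out)
  }
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) != 2)
  if (length(bad)) {
    stop("malformed compartment-map row at line ", bad[1] + 1,
         " of ", path, " (expected 2 tab-separated fields)")
  }
  measured <- vapply(parts, `[[`, "", 1)
  node <- vapply(parts, `[[`, "", 2)
  unmatched <- data.frame(measured_name = character(), node_id = character())
  if (!is.null(model)) {
    miss <- !(node %in% model$metabolites$node_id)
    if (any(miss)) {
      unmatched <- data.frame(measured_name = measured[miss], node_id = node[miss])
      warning(sum(miss), " compartment-map node id(s) not in model: ",
              paste(utils::head(unique(node[miss]), 5), collapse = ", "))
    }
  }
  out <- split(node, measured)
  out <- lapply(out, unique)
  attr(out, "unmatched") <- unmatched
  out
}
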
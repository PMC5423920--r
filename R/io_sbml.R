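# SBML Level 3 (core + fbc-v2 subset) reader/writer. Covered fields: species
# with compartment/charge/formula, reactions with stoichiometry, flux bounds
# as shared parameters, gene-product associations, and the active objective.
# Anything else present in the document (rules, events, constraints, function
# definitions) is reported as unsupported, never silently dropped.

SBML_NS_CORE <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_NS_FBC <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

xesc <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Write a model to an SBML (Level 3 + fbc) file
#'
#' Flux bounds are emitted as shared `parameter` elements referenced through
#' `fbc:lowerFluxBound`/`fbc:upperFluxBound`; GPR rules become
#' `fbc:geneProductAssociation` trees; the objective becomes the active
#' `fbc:objective`. Numbers use the shortest decimal that reparses to the
#' identical double, so [read_sbml()] recovers them exactly.
#'
#' @param model A `metabolic_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  met <- model$metabolites
  rxn <- model$reactions
  bound_vals <- sort(unique(c(rxn$lower_bound, rxn$upper_bound)))
  bound_id <- stats::setNames(sprintf("fb_%d", seq_along(bound_vals)),
                              fmt_num(bound_vals))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_NS_CORE, SBML_NS_FBC),
    '<model id="model" fbc:strict="true">',
    "<listOfCompartments>",
    sprintf('<compartment id="%s" constant="true"/>', xesc(model$compartments)),
    "</listOfCompartments>",
    "<listOfSpecies>")
  formula_attr <- ifelse(nzchar(met$formula),
                         sprintf(' fbc:chemicalFormula="%s"', xesc(met$formula)), "")
  name_attr <- ifelse(is.na(met$name), "", sprintf(' name="%s"', xesc(met$name)))
  lines <- c(lines, sprintf(
    '<species id="M_%s"%s compartment="%s" fbc:charge="%d"%s hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
    xesc(met$id), name_attr, xesc(met$compartment), as.integer(met$charge),
    formula_attr),
    "</listOfSpecies>",
    "<listOfParameters>",
    sprintf('<parameter id="%s" value="%s" constant="true"/>',
            unname(bound_id), names(bound_id)),
    "</listOfParameters>",
    "<listOfReactions>")
  for (i in seq_len(nrow(rxn))) {
    rid <- rxn$id[i]
    st <- model$stoichiometry[model$stoichiometry$reaction == rid, , drop = FALSE]
    sub <- st[st$coefficient < 0, , drop = FALSE]
    prod <- st[st$coefficient > 0, , drop = FALSE]
    nm <- if (is.na(rxn$name[i])) "" else sprintf(' name="%s"', xesc(rxn$name[i]))
    lines <- c(lines, sprintf(
      '<reaction id="R_%s"%s reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      xesc(rid), nm, tolower(rxn$lower_bound[i] < 0),
      bound_id[[fmt_num(rxn$lower_bound[i])]],
      bound_id[[fmt_num(rxn$upper_bound[i])]]))
    if (nrow(sub)) {
      lines <- c(lines, "<listOfReactants>",
        sprintf('<speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                xesc(sub$metabolite), fmt_num(-sub$coefficient)),
        "</listOfReactants>")
    }
    if (nrow(prod)) {
      lines <- c(lines, "<listOfProducts>",
        sprintf('<speciesReference species="M_%s" stoichiometry="%s" constant="true"/>',
                xesc(prod$metabolite), fmt_num(prod$coefficient)),
        "</listOfProducts>")
    }
    if (nzchar(rxn$gpr[i])) {
      lines <- c(lines, "<fbc:geneProductAssociation>",
                 gpa_xml(model$gpr_parsed[[rid]]), "</fbc:geneProductAssociation>")
    }
    lines <- c(lines, "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>")
  if (length(model$objective)) {
    lines <- c(lines,
      '<fbc:listOfObjectives fbc:activeObjective="obj">',
      '<fbc:objective fbc:id="obj" fbc:type="maximize">',
      "<fbc:listOfFluxObjectives>",
      sprintf('<fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="%s"/>',
              xesc(names(model$objective)), fmt_num(unname(model$objective))),
      "</fbc:listOfFluxObjectives>", "</fbc:objective>", "</fbc:listOfObjectives>")
  }
  if (length(model$genes)) {
    lines <- c(lines, "<fbc:listOfGeneProducts>",
      sprintf('<fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
              xesc(gsub("[^A-Za-z0-9_]", "_", model$genes)), xesc(model$genes)),
      "</fbc:listOfGeneProducts>")
  }
  lines <- c(lines, "</model>", "</sbml>")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

gpa_xml <- function(node) {
  if (node$type == "leaf") {
    return(sprintf('<fbc:geneProductRef fbc:geneProduct="G_%s"/>',
                   xesc(gsub("[^A-Za-z0-9_]", "_", node$gene))))
  }
  tag <- if (node$type == "and") "fbc:and" else "fbc:or"
  c(sprintf("<%s>", tag), unlist(lapply(node$children, gpa_xml)),
    sprintf("</%s>", tag))
}

strip_prefix <- function(x, prefix) sub(paste0("^", prefix), "", x)

#' Read a model from an SBML (Level 3 + fbc subset) file
#'
#' Inverts [write_sbml()] exactly for the fields the model container carries.
#' Unsupported SBML constructs (rules, events, constraints, function
#' definitions) abort with a message naming them; a species without a
#' compartment is an error.
#'
#' @param path Path to the SBML file.
#' @return A validated `metabolic_model`.
#' @export
read_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  ln <- function(tag) sprintf("*[local-name()='%s']", tag)
  unsupported <- c("listOfRules", "listOfEvents", "listOfConstraints",
                   "listOfFunctionDefinitions", "listOfInitialAssignments")
  present <- unsupported[vapply(unsupported, function(tag) {
    length(xml2::xml_find_all(doc, paste0(".//", ln(tag)))) > 0
  }, logical(1))]
  if (length(present)) {
    stop("unsupported SBML constructs: ", paste(present, collapse = ", "),
         call. = FALSE)
  }
  comp_nodes <- xml2::xml_find_all(doc, paste0(".//", ln("listOfCompartments"), "/", ln("compartment")))
  compartments <- xml2::xml_attr(comp_nodes, "id")

  sp <- xml2::xml_find_all(doc, paste0(".//", ln("listOfSpecies"), "/", ln("species")))
  sp_comp <- xml2::xml_attr(sp, "compartment")
  if (anyNA(sp_comp)) {
    stop("species missing compartment: ",
         paste(xml2::xml_attr(sp, "id")[is.na(sp_comp)], collapse = ", "),
         call. = FALSE)
  }
  charge <- xml2::xml_attr(sp, "charge")
  formula <- xml2::xml_attr(sp, "chemicalFormula")
  metabolites <- tibble::tibble(
    id = strip_prefix(xml2::xml_attr(sp, "id"), "M_"),
    name = xml2::xml_attr(sp, "name"),
    compartment = sp_comp,
    formula = ifelse(is.na(formula), "", formula),
    charge = ifelse(is.na(charge), 0L, as.integer(charge)))

  params <- xml2::xml_find_all(doc, paste0(".//", ln("listOfParameters"), "/", ln("parameter")))
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  gp <- xml2::xml_find_all(doc, paste0(".//", ln("listOfGeneProducts"), "/", ln("geneProduct")))
  gene_label <- stats::setNames(xml2::xml_attr(gp, "label"),
                                xml2::xml_attr(gp, "id"))

  rx_nodes <- xml2::xml_find_all(doc, paste0(".//", ln("listOfReactions"), "/", ln("reaction")))
  rxn_rows <- list(); st_rows <- list()
  for (node in rx_nodes) {
    rid <- strip_prefix(xml2::xml_attr(node, "id"), "R_")
    lbp <- xml2::xml_attr(node, "lowerFluxBound")
    ubp <- xml2::xml_attr(node, "upperFluxBound")
    if (is.na(lbp) || is.na(ubp) || !lbp %in% names(pval) || !ubp %in% names(pval)) {
      stop("reaction ", rid, " lacks resolvable flux-bound parameters",
           call. = FALSE)
    }
    subs <- xml2::xml_find_all(node, paste0("./", ln("listOfReactants"), "/", ln("speciesReference")))
    prods <- xml2::xml_find_all(node, paste0("./", ln("listOfProducts"), "/", ln("speciesReference")))
    st_rows[[rid]] <- tibble::tibble(
      reaction = rid,
      metabolite = strip_prefix(
        c(xml2::xml_attr(subs, "species"), xml2::xml_attr(prods, "species")), "M_"),
      coefficient = c(-as.numeric(xml2::xml_attr(subs, "stoichiometry")),
                      as.numeric(xml2::xml_attr(prods, "stoichiometry"))))
    gpa <- xml2::xml_find_first(node, paste0("./", ln("geneProductAssociation"), "/*"))
    gpr_text <- if (inherits(gpa, "xml_missing")) "" else {
      format_gpr(gpa_parse(gpa, gene_label))
    }
    rxn_rows[[rid]] <- tibble::tibble(
      id = rid, name = xml2::xml_attr(node, "name"),
      lower_bound = unname(pval[[lbp]]), upper_bound = unname(pval[[ubp]]),
      gpr = gpr_text, subsystem = NA_character_)
  }
  fo <- xml2::xml_find_all(doc, paste0(".//", ln("listOfFluxObjectives"), "/", ln("fluxObjective")))
  objective <- if (length(fo)) {
    stats::setNames(as.numeric(xml2::xml_attr(fo, "coefficient")),
                    strip_prefix(xml2::xml_attr(fo, "reaction"), "R_"))
  } else NULL
  metabolic_model(
    reactions = dplyr::bind_rows(rxn_rows),
    metabolites = metabolites,
    stoichiometry = dplyr::bind_rows(st_rows),
    genes = if (length(gene_label)) unname(gene_label) else NULL,
    objective = objective,
    compartments = if (length(compartments)) compartments else NULL)
}

gpa_parse <- function(node, gene_label) {
  tag <- xml2::xml_name(node)
  if (tag == "geneProductRef") {
    gid <- xml2::xml_attr(node, "geneProduct")
    lab <- if (gid %in% names(gene_label)) gene_label[[gid]] else strip_prefix(gid, "G_")
    return(structure(list(type = "leaf", gene = lab), class = "gpr"))
  }
  kids <- lapply(xml2::xml_children(node), gpa_parse, gene_label = gene_label)
  type <- if (tag == "and") "and" else if (tag == "or") "or" else {
    stop("unsupported gene-association element: ", tag, call. = FALSE)
  }
  gpr_normalize(list(type = type, children = kids))
}
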
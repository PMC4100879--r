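# SBML read/write for Recon1-style constraint-based models.
#
# Reading handles the two dialects genome-scale reconstructions actually use:
#  * COBRA SBML Level 2: bounds as LOWER_BOUND/UPPER_BOUND kineticLaw
#    parameters, GPR and subsystem in the notes body
#    (GENE_ASSOCIATION: ... / SUBSYSTEM: ...).
#  * SBML Level 3 + fbc: bounds via fbc:lowerFluxBound parameter references,
#    GPR as an fbc:geneProductAssociation tree.
# Writing emits the Level 2 COBRA dialect, which round-trips through the
# reader.

#' @rdname read_network
#' @param extracellular compartment id treated as the shared extracellular
#'   compartment (mapped to `"e"`).
#' @param strip_prefixes drop the BiGG `R_`/`M_` id prefixes and the trailing
#'   `_<compartment>` of species ids.
#' @param default_bound magnitude used when a bound is not declared.
#' @export
read_sbml <- function(path, extracellular = "e", strip_prefixes = TRUE,
                      default_bound = 1000) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("parse error in ", path, ": ",
                                           conditionMessage(e)))
  ns <- xml2::xml_ns(doc)
  model <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (inherits(model, "xml_missing")) stop("parse error: no <model> element")

  strip_m <- function(id, comp) {
    if (!strip_prefixes) return(id)
    id <- sub("^M_", "", id)
    sub(paste0("_", comp, "$"), "", id)
  }

  sp_nodes <- xml2::xml_find_all(
    model, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  sp_id <- xml2::xml_attr(sp_nodes, "id")
  sp_comp <- xml2::xml_attr(sp_nodes, "compartment")
  sp_boundary <- xml2::xml_attr(sp_nodes, "boundaryCondition") %in% "true"
  comp <- ifelse(sp_comp == extracellular, "e", sp_comp)
  base <- mapply(strip_m, sp_id, sp_comp)
  metabolites <- tibble::tibble(
    sbml_id = sp_id,
    id = paste0(base, "[", comp, "]"),
    name = unname(base),
    compartment = comp)[!sp_boundary, ]

  # fbc parameter table for L3 bound references
  par_nodes <- xml2::xml_find_all(
    model, ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_val <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))

  parse_gpr_fbc <- function(node) {
    nm <- xml2::xml_name(node)
    kids <- xml2::xml_children(node)
    if (nm == "geneProductRef") return(xml2::xml_attr(node, "geneProduct"))
    inner <- vapply(kids, parse_gpr_fbc, character(1))
    if (nm == "and") paste0("(", paste(inner, collapse = " and "), ")")
    else if (nm == "or") paste0("(", paste(inner, collapse = " or "), ")")
    else if (length(inner)) inner[[1]] else ""
  }

  rx_nodes <- xml2::xml_find_all(
    model, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  rows <- purrr::map(rx_nodes, function(node) {
    rid <- xml2::xml_attr(node, "id")
    if (strip_prefixes) rid <- sub("^R_", "", rid)
    rev_attr <- xml2::xml_attr(node, "reversible")
    reversible <- is.na(rev_attr) | rev_attr == "true"

    get_side <- function(tag, sign) {
      refs <- xml2::xml_find_all(
        node, paste0(".//*[local-name()='", tag,
                     "']/*[local-name()='speciesReference']"))
      if (!length(refs)) return(NULL)
      stoi <- xml2::xml_attr(refs, "stoichiometry")
      stoi[is.na(stoi)] <- "1"
      tibble::tibble(sbml_species = xml2::xml_attr(refs, "species"),
                     coefficient = sign * as.numeric(stoi))
    }
    st <- dplyr::bind_rows(get_side("listOfReactants", -1),
                           get_side("listOfProducts", +1))

    # bounds: kineticLaw parameters, else fbc references, else reversibility
    lb <- NA_real_; ub <- NA_real_
    kl <- xml2::xml_find_all(
      node, ".//*[local-name()='kineticLaw']//*[local-name()='parameter']")
    if (length(kl)) {
      kid <- xml2::xml_attr(kl, "id")
      kv <- as.numeric(xml2::xml_attr(kl, "value"))
      if ("LOWER_BOUND" %in% kid) lb <- kv[match("LOWER_BOUND", kid)]
      if ("UPPER_BOUND" %in% kid) ub <- kv[match("UPPER_BOUND", kid)]
    }
    lbr <- xml2::xml_attr(node, "lowerFluxBound")
    ubr <- xml2::xml_attr(node, "upperFluxBound")
    if (is.na(lb) && !is.na(lbr)) lb <- par_val[[lbr]]
    if (is.na(ub) && !is.na(ubr)) ub <- par_val[[ubr]]
    if (is.na(lb)) lb <- if (reversible) -default_bound else 0
    if (is.na(ub)) ub <- default_bound

    note_lines <- xml2::xml_text(xml2::xml_find_all(
      node, ".//*[local-name()='notes']//*[local-name()='p']"))
    grab <- function(field) {
      hit <- stringr::str_match(note_lines, paste0("^", field, ":\\s*(.*)$"))
      out <- stringr::str_trim(stats::na.omit(hit[, 2]))
      if (length(out)) out[1] else ""
    }
    gpr <- grab("GENE_ASSOCIATION")
    subsystem <- grab("SUBSYSTEM")
    gpa <- xml2::xml_find_first(
      node, ".//*[local-name()='geneProductAssociation']")
    if (gpr == "" && !inherits(gpa, "xml_missing")) {
      kids <- xml2::xml_children(gpa)
      if (length(kids)) gpr <- parse_gpr_fbc(kids[[1]])
    }
    list(reaction = tibble::tibble(
           id = rid, lower_bound = lb, upper_bound = ub,
           reversible = lb < 0, gpr = gpr, subsystem = subsystem),
         stoich = if (!is.null(st))
           dplyr::mutate(st, reaction_id = rid) else NULL)
  })

  stoich <- dplyr::bind_rows(purrr::map(rows, "stoich"))
  # drop boundary species references (system-boundary pool of exchanges)
  stoich <- dplyr::left_join(stoich,
                             dplyr::select(metabolites, sbml_id, id),
                             by = c("sbml_species" = "sbml_id"))
  unknown <- stoich$sbml_species[is.na(stoich$id) &
                                   !stoich$sbml_species %in% sp_id]
  if (length(unknown))
    stop("integrity error: reaction references undeclared species: ",
         paste(unique(unknown), collapse = ", "))
  stoich <- stoich[!is.na(stoich$id), c("reaction_id", "id", "coefficient")]
  names(stoich)[2] <- "metabolite_id"

  metabolic_network(
    reactions = dplyr::bind_rows(purrr::map(rows, "reaction")),
    metabolites = dplyr::select(metabolites, -sbml_id),
    stoichiometry = stoich,
    name = xml2::xml_attr(model, "id") %||% basename(path))
}

#' Write a network as COBRA-dialect SBML Level 2
#'
#' @param net a [metabolic_network()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(net, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)
  met_sid <- stats::setNames(
    paste0("M_", sid(gsub("\\[([^]]+)\\]", "_\\1", net$metabolites$id))),
    net$metabolites$id)
  comps <- unique(net$metabolites$compartment)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    sprintf('<model id="%s">', sid(net$name)),
    "<listOfCompartments>",
    sprintf('<compartment id="%s"/>', sid(comps)),
    "</listOfCompartments>",
    "<listOfSpecies>",
    sprintf('<species id="%s" name="%s" compartment="%s"/>',
            met_sid[net$metabolites$id], esc(net$metabolites$name),
            sid(net$metabolites$compartment)),
    "</listOfSpecies>",
    "<listOfReactions>")
  st <- split(net$stoichiometry, net$stoichiometry$reaction_id)
  for (i in seq_len(n_reactions(net))) {
    r <- net$reactions[i, ]
    rows <- st[[r$id]]
    refs <- function(sel) {
      if (is.null(rows) || !any(sel)) return(character())
      sprintf('<speciesReference species="%s" stoichiometry="%s"/>',
              met_sid[rows$metabolite_id[sel]],
              format_num(abs(rows$coefficient[sel])))
    }
    lines <- c(
      lines,
      sprintf('<reaction id="R_%s" reversible="%s">',
              sid(r$id), tolower(as.character(r$reversible))),
      "<notes><body xmlns=\"http://www.w3.org/1999/xhtml\">",
      sprintf("<p>GENE_ASSOCIATION: %s</p>", esc(r$gpr)),
      sprintf("<p>SUBSYSTEM: %s</p>", esc(r$subsystem)),
      "</body></notes>",
      if (!is.null(rows) && any(rows$coefficient < 0))
        c("<listOfReactants>", refs(rows$coefficient < 0),
          "</listOfReactants>"),
      if (!is.null(rows) && any(rows$coefficient > 0))
        c("<listOfProducts>", refs(rows$coefficient > 0),
          "</listOfProducts>"),
      "<kineticLaw><math xmlns=\"http://www.w3.org/1998/Math/MathML\"><ci>FLUX_VALUE</ci></math>",
      "<listOfParameters>",
      sprintf('<parameter id="LOWER_BOUND" value="%s"/>',
              format_num(r$lower_bound)),
      sprintf('<parameter id="UPPER_BOUND" value="%s"/>',
              format_num(r$upper_bound)),
      "</listOfParameters></kineticLaw>",
      "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>", "</model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}
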
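#' Export the network to SBML Level 3 (best effort)
#'
#' Writes the species, reactions and Michaelis-Menten kinetic laws (as
#' MathML products of saturation terms) to an SBML Level 3 Version 2
#' document for interoperability with pathway tools. Requires the `xml2`
#' package.
#'
#' @param model a `metabolic_model`.
#' @param path output file path (.xml).
#' @param params parameter vector supplying Km/vmax values.
#' @return The path, invisibly.
#' @export
export_sbml <- function(model, path, params = default_parameters(model)) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("export_sbml requires the 'xml2' package")
  }
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version2/core",
    level = "3", version = "2"
  )
  mdl <- xml2::xml_add_child(doc, "model", id = model$name,
                             substanceUnits = "millimole",
                             timeUnits = "hour")
  comp <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(comp, "compartment", id = "cell", size = "1",
                      constant = "true")
  los <- xml2::xml_add_child(mdl, "listOfSpecies")
  all_states <- rbind(
    model$species[, c("id", "c0")],
    data.frame(id = model$auxiliary, c0 = 0)
  )
  for (i in seq_len(nrow(all_states))) {
    xml2::xml_add_child(
      los, "species", id = all_states$id[i], compartment = "cell",
      initialConcentration = format(all_states$c0[i]),
      hasOnlySubstanceUnits = "false",
      boundaryCondition = "false", constant = "false")
  }
  lop <- xml2::xml_add_child(mdl, "listOfParameters")
  kin <- params[parameter_kind(names(params)) != "initial_concentration"]
  for (nm in names(kin)) {
    xml2::xml_add_child(lop, "parameter", id = nm,
                        value = format(kin[[nm]]), constant = "true")
  }
  lor <- xml2::xml_add_child(mdl, "listOfReactions")
  laws <- stats::setNames(model$flux_laws,
                          vapply(model$flux_laws, `[[`, character(1), "id"))
  for (r in model$reactions) {
    st <- unlist(r$stoichiometry)
    rx <- xml2::xml_add_child(lor, "reaction", id = paste0("R_", r$flux),
                              reversible = tolower(as.character(
                                !is.null(laws[[r$flux]]$reverse))))
    lre <- xml2::xml_add_child(rx, "listOfReactants")
    lpr <- xml2::xml_add_child(rx, "listOfProducts")
    for (sp in names(st)) {
      parent <- if (st[[sp]] < 0) lre else lpr
      xml2::xml_add_child(parent, "speciesReference", species = sp,
                          stoichiometry = format(abs(st[[sp]])),
                          constant = "true")
    }
    kl <- xml2::xml_add_child(rx, "kineticLaw")
    math <- xml2::xml_add_child(
      kl, "math", xmlns = "http://www.w3.org/1998/Math/MathML")
    add_law_math(math, laws[[r$flux]])
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

# <apply><times/> vmax, [S]/(Km+[S]) ... </apply>, minus reverse if present
add_law_math <- function(math, law) {
  side_apply <- function(parent, side) {
    ap <- xml2::xml_add_child(parent, "apply")
    xml2::xml_add_child(ap, "times")
    ci(ap, paste0("vmax_", side$vmax))
    for (s in as.character(side$substrates)) {
      frac <- xml2::xml_add_child(ap, "apply")
      xml2::xml_add_child(frac, "divide")
      ci(frac, s)
      plus <- xml2::xml_add_child(frac, "apply")
      xml2::xml_add_child(plus, "plus")
      ci(plus, paste0("Km_", s))
      ci(plus, s)
    }
  }
  if (is.null(law$reverse)) {
    side_apply(math, law$forward)
  } else {
    ap <- xml2::xml_add_child(math, "apply")
    xml2::xml_add_child(ap, "minus")
    side_apply(ap, law$forward)
    side_apply(ap, law$reverse)
  }
}

ci <- function(parent, name) {
  node <- xml2::xml_add_child(parent, "ci")
  xml2::xml_set_text(node, name)
  node
}
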
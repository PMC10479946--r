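#' Read a metabolic model from SBML or COBRA-style JSON
#'
#' The format is inferred from the file extension unless given. The JSON
#' dialect mirrors the community COBRA JSON schema (`metabolites`,
#' `reactions` with `metabolites` coefficient maps, `gene_reaction_rule`,
#' `lower_bound`/`upper_bound`, `objective_coefficient`, `subsystem`), with a
#' `schema_version` field, so genome-scale files in that dialect load
#' unchanged. SBML support targets Level 3 with the `fbc` package (flux
#' bounds as parameters, GPRs as `geneProductAssociation` trees).
#'
#' @param path file path.
#' @param format `"auto"`, `"json"` or `"sbml"`.
#' @return a `metabolic_model`.
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  switch(format, json = read_model_json(path), sbml = read_model_sbml(path))
}

#' Write a metabolic model to SBML or JSON
#'
#' @param model a `metabolic_model`.
#' @param path destination file.
#' @param format `"auto"` (from extension), `"json"` or `"sbml"`.
#' @return the path, invisibly.
#' @export
save_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  switch(format, json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

MODEL_SCHEMA_VERSION <- 1L

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed JSON in '", path, "': ",
                                           conditionMessage(e)))
  for (field in c("metabolites", "reactions")) {
    if (is.null(doc[[field]])) stop("model JSON missing '", field, "' in ", path)
  }
  mets <- data.frame(
    id = vapply(doc$metabolites, function(m) m$id, character(1)),
    name = vapply(doc$metabolites, function(m) m$name %||% m$id, character(1)),
    compartment = vapply(doc$metabolites, function(m) m$compartment %||% "", character(1)),
    stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = vapply(doc$reactions, function(r) r$id, character(1)),
    lower_bound = vapply(doc$reactions, function(r) as.numeric(r$lower_bound %||% 0), numeric(1)),
    upper_bound = vapply(doc$reactions, function(r) as.numeric(r$upper_bound %||% 1000), numeric(1)),
    gpr = vapply(doc$reactions, function(r) r$gene_reaction_rule %||% "", character(1)),
    subsystem = vapply(doc$reactions, function(r) r$subsystem %||% "", character(1)),
    objective_coef = vapply(doc$reactions, function(r) as.numeric(r$objective_coefficient %||% 0), numeric(1)),
    stringsAsFactors = FALSE)
  stoich <- lapply(doc$reactions, function(r) {
    coefs <- unlist(r$metabolites %||% list())
    if (is.null(coefs)) numeric() else coefs
  })
  names(stoich) <- rxns$id
  genes <- if (!is.null(doc$genes)) {
    vapply(doc$genes, function(g) if (is.list(g)) g$id else g, character(1))
  } else NULL
  comps <- if (!is.null(doc$compartments)) names(doc$compartments) else NULL
  metabolic_model(id = doc$id %||% tools::file_path_sans_ext(basename(path)),
                  metabolites = mets, reactions = rxns, stoichiometry = stoich,
                  genes = genes, compartments = comps)
}

write_model_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    list(id = m$id, name = m$name, compartment = m$compartment)
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    col <- model$S[, i]
    nz <- which(col != 0)
    out <- list(id = r$id,
                metabolites = as.list(stats::setNames(as.numeric(col[nz]),
                                                      rownames(model$S)[nz])),
                lower_bound = r$lower_bound, upper_bound = r$upper_bound,
                gene_reaction_rule = r$gpr, subsystem = r$subsystem)
    if (r$objective_coef != 0) out$objective_coefficient <- r$objective_coef
    out
  })
  doc <- list(schema_version = MODEL_SCHEMA_VERSION,
              id = model$id,
              compartments = as.list(stats::setNames(model$compartments,
                                                     model$compartments)),
              metabolites = mets,
              reactions = rxns,
              genes = lapply(model$genes, function(g) list(id = g)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- SBML L3 + fbc ---------------------------------------------------------

SBML_NS <- c(sbml = "http://www.sbml.org/sbml/level3/version1/core",
             fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed SBML in '", path, "': ",
                                           conditionMessage(e)))
  mdl <- xml2::xml_find_first(doc, ".//sbml:model", SBML_NS)
  if (inherits(mdl, "xml_missing")) stop("no <model> element in ", path)

  comp_nodes <- xml2::xml_find_all(mdl, ".//sbml:listOfCompartments/sbml:compartment", SBML_NS)
  comps <- xml2::xml_attr(comp_nodes, "id")

  sp <- xml2::xml_find_all(mdl, ".//sbml:listOfSpecies/sbml:species", SBML_NS)
  mets <- data.frame(id = xml2::xml_attr(sp, "id"),
                     name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                                   xml2::xml_attr(sp, "id"),
                                   xml2::xml_attr(sp, "name")),
                     compartment = xml2::xml_attr(sp, "compartment"),
                     stringsAsFactors = FALSE)

  params <- xml2::xml_find_all(mdl, ".//sbml:listOfParameters/sbml:parameter", SBML_NS)
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  rx <- xml2::xml_find_all(mdl, ".//sbml:listOfReactions/sbml:reaction", SBML_NS)
  n <- length(rx)
  ids <- xml2::xml_attr(rx, "id")
  lb <- ub <- numeric(n); gpr <- subsys <- character(n)
  stoich <- vector("list", n)
  for (i in seq_len(n)) {
    node <- rx[[i]]
    lbref <- xml2::xml_attr(node, "fbc:lowerFluxBound", ns = SBML_NS)
    ubref <- xml2::xml_attr(node, "fbc:upperFluxBound", ns = SBML_NS)
    lb[i] <- if (!is.na(lbref) && lbref %in% names(pval)) pval[[lbref]] else -1000
    ub[i] <- if (!is.na(ubref) && ubref %in% names(pval)) pval[[ubref]] else 1000
    reac <- xml2::xml_find_all(node, "./sbml:listOfReactants/sbml:speciesReference", SBML_NS)
    prod <- xml2::xml_find_all(node, "./sbml:listOfProducts/sbml:speciesReference", SBML_NS)
    coefs <- c(stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                               xml2::xml_attr(reac, "species")),
               stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                               xml2::xml_attr(prod, "species")))
    if (length(coefs)) {
      bad <- setdiff(names(coefs), mets$id)
      if (length(bad)) {
        stop("reaction '", ids[i], "' in ", path,
             " references undeclared species: ", paste(bad, collapse = ", "))
      }
      coefs <- tapply(coefs, names(coefs), sum)  # merge duplicate refs
      stoich[[i]] <- stats::setNames(as.numeric(coefs), names(coefs))
    } else stoich[[i]] <- numeric()
    gpa <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", SBML_NS)
    gpr[i] <- if (inherits(gpa, "xml_missing")) "" else {
      gpr_deparse(sbml_gpa_to_tree(xml2::xml_child(gpa)))
    }
    note <- xml2::xml_find_first(node, ".//*[local-name()='p']")
    subsys[i] <- if (!inherits(note, "xml_missing") &&
                     grepl("^SUBSYSTEM:", xml2::xml_text(note))) {
      trimws(sub("^SUBSYSTEM:", "", xml2::xml_text(note)))
    } else ""
  }
  names(stoich) <- ids

  objcoef <- stats::setNames(rep(0, n), ids)
  fo <- xml2::xml_find_all(mdl, ".//fbc:listOfObjectives/fbc:objective/fbc:listOfFluxObjectives/fbc:fluxObjective", SBML_NS)
  for (node in fo) {
    rid <- xml2::xml_attr(node, "fbc:reaction", ns = SBML_NS)
    objcoef[rid] <- as.numeric(xml2::xml_attr(node, "fbc:coefficient", ns = SBML_NS))
  }

  gp <- xml2::xml_find_all(mdl, ".//fbc:listOfGeneProducts/fbc:geneProduct", SBML_NS)
  genes <- xml2::xml_attr(gp, "fbc:label", ns = SBML_NS)
  genes <- genes[!is.na(genes)]

  rxns <- data.frame(id = ids, lower_bound = lb, upper_bound = ub, gpr = gpr,
                     subsystem = subsys, objective_coef = as.numeric(objcoef),
                     stringsAsFactors = FALSE)
  metabolic_model(id = xml2::xml_attr(mdl, "id") %||% basename(path),
                  metabolites = mets, reactions = rxns, stoichiometry = stoich,
                  genes = if (length(genes)) genes else NULL,
                  compartments = if (length(comps)) comps else NULL)
}

sbml_gpa_to_tree <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    lab <- xml2::xml_attr(node, "fbc:label", ns = SBML_NS)
    if (is.na(lab)) lab <- xml2::xml_attr(node, "fbc:geneProduct", ns = SBML_NS)
    return(sub("^G_", "", lab))
  }
  if (nm %in% c("and", "or")) {
    return(list(op = nm,
                args = lapply(xml2::xml_children(node), sbml_gpa_to_tree)))
  }
  stop("unsupported geneProductAssociation node: ", nm)
}

write_model_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  num <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  con <- c(sprintf('<?xml version="1.0" encoding="UTF-8"?>'),
           sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
                   SBML_NS[["sbml"]], SBML_NS[["fbc"]]),
           sprintf('  <model id="%s" fbc:strict="true">', esc(model$id)))
  con <- c(con, '    <listOfCompartments>',
           sprintf('      <compartment id="%s" constant="true"/>',
                   esc(model$compartments)),
           '    </listOfCompartments>')
  con <- c(con, '    <listOfSpecies>',
           sprintf('      <species id="%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
                   esc(model$metabolites$id), esc(model$metabolites$name),
                   esc(model$metabolites$compartment)),
           '    </listOfSpecies>')
  bnd_ids <- character(0); bnd_vals <- numeric(0)
  bound_par <- function(v) {
    hit <- which(bnd_vals == v)
    if (length(hit)) return(bnd_ids[hit[1]])
    id <- sprintf("fb_%d", length(bnd_ids) + 1L)
    bnd_ids <<- c(bnd_ids, id); bnd_vals <<- c(bnd_vals, v)
    id
  }
  rxn_lines <- character(0)
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    lbp <- bound_par(r$lower_bound); ubp <- bound_par(r$upper_bound)
    rxn_lines <- c(rxn_lines, sprintf(
      '      <reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      esc(r$id), tolower(r$lower_bound < 0), lbp, ubp))
    if (nzchar(r$subsystem)) {
      rxn_lines <- c(rxn_lines,
        '        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
        sprintf('          <p>SUBSYSTEM: %s</p>', esc(r$subsystem)),
        '        </body></notes>')
    }
    col <- model$S[, i]; nz <- which(col != 0)
    reac <- nz[col[nz] < 0]; prod <- nz[col[nz] > 0]
    if (length(reac)) {
      rxn_lines <- c(rxn_lines, '        <listOfReactants>',
        sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                esc(rownames(model$S)[reac]), num(-col[reac])),
        '        </listOfReactants>')
    }
    if (length(prod)) {
      rxn_lines <- c(rxn_lines, '        <listOfProducts>',
        sprintf('          <speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                esc(rownames(model$S)[prod]), num(col[prod])),
        '        </listOfProducts>')
    }
    tree <- gpr_parse(r$gpr)
    if (!is.null(tree)) {
      rxn_lines <- c(rxn_lines, '        <fbc:geneProductAssociation>',
                     sbml_tree_to_gpa(tree, indent = "          "),
                     '        </fbc:geneProductAssociation>')
    }
    rxn_lines <- c(rxn_lines, '      </reaction>')
  }
  con <- c(con, '    <listOfParameters>',
           sprintf('      <parameter id="%s" value="%s" constant="true"/>',
                   bnd_ids, num(bnd_vals)),
           '    </listOfParameters>',
           '    <listOfReactions>', rxn_lines, '    </listOfReactions>')
  obj <- objective_ids(model)
  if (length(obj)) {
    coefs <- model$reactions$objective_coef[match(obj, model$reactions$id)]
    con <- c(con,
      '    <fbc:listOfObjectives fbc:activeObjective="obj">',
      '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
      '        <fbc:listOfFluxObjectives>',
      sprintf('          <fbc:fluxObjective fbc:reaction="%s" fbc:coefficient="%s"/>',
              esc(obj), num(coefs)),
      '        </fbc:listOfFluxObjectives>',
      '      </fbc:objective>',
      '    </fbc:listOfObjectives>')
  }
  if (length(model$genes)) {
    con <- c(con, '    <fbc:listOfGeneProducts>',
      sprintf('      <fbc:geneProduct fbc:id="G_%s" fbc:label="%s"/>',
              esc(model$genes), esc(model$genes)),
      '    </fbc:listOfGeneProducts>')
  }
  con <- c(con, '  </model>', '</sbml>')
  writeLines(con, path)
  invisible(path)
}

sbml_tree_to_gpa <- function(tree, indent) {
  if (is.character(tree)) {
    return(sprintf('%s<fbc:geneProductRef fbc:geneProduct="G_%s"/>', indent, tree))
  }
  inner <- unlist(lapply(tree$args, sbml_tree_to_gpa, indent = paste0(indent, "  ")))
  c(sprintf("%s<fbc:%s>", indent, tree$op), inner,
    sprintf("%s</fbc:%s>", indent, tree$op))
}
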
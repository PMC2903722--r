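# SBML Level 2 model reading, writing and structural validation.  The model
# is both an input (its species and reactions are queried) and the output
# target (annotations, species and skeleton reactions are added), so it gets
# a dedicated in-memory representation with round-trip fidelity for the
# attributes and annotation blocks this package touches.

SBML_L2_NS <- "http://www.sbml.org/sbml/level2/version%d"
RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
BQBIOL_NS <- "http://biomodels.net/biology-qualifiers/"

#' Read an SBML Level 2 model
#'
#' Loads compartments, species (with name, compartment, initial amount, SBO
#' term and MIRIAM annotation block) and reactions (reactant, product and
#' modifier species references).  The document is structurally validated on
#' load.
#'
#' @param path SBML file path.
#' @return An object of class `sbml_model`.
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop(sprintf("invalid SBML in '%s': %s", path, conditionMessage(e)))
  })
  root <- xml2::xml_root(doc)
  if (local_tag(root) != "sbml") {
    stop(sprintf("invalid SBML in '%s': root element is '%s'", path, local_tag(root)))
  }
  at <- function(node, attr) {
    v <- xml_attr_local(node, attr)
    if (is_blank(v)) NULL else v
  }
  level <- as.integer(at(root, "level") %||% "2")
  version <- as.integer(at(root, "version") %||% "4")
  if (is.na(level) || level != 2L) {
    stop(sprintf("invalid SBML in '%s': only Level 2 is supported", path))
  }
  mnode <- xml2::xml_find_first(root, "./*[local-name()='model']")
  if (inherits(mnode, "xml_missing")) {
    stop(sprintf("invalid SBML in '%s': no model element", path))
  }
  model <- list(
    level = level, version = version,
    id = at(mnode, "id"),
    name = at(mnode, "name"),
    compartments = list(), species = list(), reactions = list()
  )
  for (cn in xml2::xml_find_all(mnode, ".//*[local-name()='listOfCompartments']/*[local-name()='compartment']")) {
    model$compartments[[length(model$compartments) + 1L]] <- list(
      id = at(cn, "id"),
      name = at(cn, "name"),
      size = at(cn, "size")
    )
  }
  for (sn in xml2::xml_find_all(mnode, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")) {
    model$species[[length(model$species) + 1L]] <- list(
      id = at(sn, "id"),
      metaid = at(sn, "metaid"),
      name = at(sn, "name"),
      compartment = at(sn, "compartment"),
      initialAmount = at(sn, "initialAmount"),
      sboTerm = at(sn, "sboTerm"),
      annotations = read_annotation_block(sn)
    )
  }
  for (rn in xml2::xml_find_all(mnode, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")) {
    refs <- function(listname, refname) {
      nodes <- xml2::xml_find_all(rn, sprintf(
        "./*[local-name()='%s']/*[local-name()='%s']", listname, refname))
      vapply(nodes, function(n) at(n, "species"), character(1))
    }
    model$reactions[[length(model$reactions) + 1L]] <- list(
      id = at(rn, "id"),
      metaid = at(rn, "metaid"),
      name = at(rn, "name"),
      reversible = identical(at(rn, "reversible"), "true"),
      reactants = refs("listOfReactants", "speciesReference"),
      products = refs("listOfProducts", "speciesReference"),
      modifiers = refs("listOfModifiers", "modifierSpeciesReference"),
      annotations = read_annotation_block(rn)
    )
  }
  model <- structure(model, class = "sbml_model")
  v <- validate_sbml(model)
  if (!v$valid) {
    stop(sprintf("invalid SBML in '%s':\n  %s", path,
                 paste(v$errors, collapse = "\n  ")))
  }
  model
}

read_annotation_block <- function(node) {
  out <- list()
  descs <- xml2::xml_find_all(node, "./*[local-name()='annotation']/*[local-name()='RDF']/*[local-name()='Description']")
  for (d in descs) {
    for (q in element_children(d)) {
      qualifier <- local_tag(q)
      if (!qualifier %in% MIRIAM_QUALIFIERS) next
      lis <- xml2::xml_find_all(q, "./*[local-name()='Bag']/*[local-name()='li']")
      for (li in lis) {
        uri <- xml_attr_local(li, "resource")
        if (!is_blank(uri)) {
          out[[length(out) + 1L]] <- list(qualifier = qualifier, uri = uri)
        }
      }
    }
  }
  out
}

#' @export
print.sbml_model <- function(x, ...) {
  cat(sprintf("<sbml_model '%s': %d compartments, %d species, %d reactions>\n",
              x$id %||% "?", length(x$compartments), length(x$species),
              length(x$reactions)))
  invisible(x)
}

species_ids <- function(model) {
  vapply(model$species, function(s) s$id %||% NA_character_, character(1))
}
reaction_ids <- function(model) {
  vapply(model$reactions, function(r) r$id %||% NA_character_, character(1))
}
get_species <- function(model, id) {
  for (s in model$species) if (identical(s$id, id)) return(s)
  NULL
}
reaction_species <- function(reaction, roles = c("reactants", "products", "modifiers")) {
  unique(unlist(reaction[roles], use.names = FALSE))
}

# ---------------------------------------------------------------------------
# serialization

fmt_attr <- function(name, value) {
  if (is_blank(value)) "" else sprintf(' %s="%s"', name, xml_escape(value))
}

annotation_lines <- function(metaid, annotations, indent) {
  if (!length(annotations)) return(character())
  pad <- strrep(" ", indent)
  quals <- unique(vapply(annotations, `[[`, character(1), "qualifier"))
  out <- c(
    paste0(pad, "<annotation>"),
    paste0(pad, sprintf('  <rdf:RDF xmlns:rdf="%s" xmlns:bqbiol="%s">', RDF_NS, BQBIOL_NS)),
    paste0(pad, sprintf('    <rdf:Description rdf:about="#%s">', xml_escape(metaid)))
  )
  for (q in quals) {
    out <- c(out, paste0(pad, sprintf("      <bqbiol:%s>", q)),
             paste0(pad, "        <rdf:Bag>"))
    for (a in annotations) {
      if (a$qualifier == q) {
        out <- c(out, paste0(pad, sprintf('          <rdf:li rdf:resource="%s"/>',
                                          xml_escape(a$uri))))
      }
    }
    out <- c(out, paste0(pad, "        </rdf:Bag>"),
             paste0(pad, sprintf("      </bqbiol:%s>", q)))
  }
  c(out,
    paste0(pad, "    </rdf:Description>"),
    paste0(pad, "  </rdf:RDF>"),
    paste0(pad, "</annotation>"))
}

#' Write an SBML Level 2 model
#'
#' Deterministic serialization: element and attribute order are fixed, and
#' MIRIAM annotations are written in the standard RDF / biology-qualifier
#' block layout.  Species that carry annotations but no `metaid` receive one
#' derived from their id.
#'
#' @param model An `sbml_model`.
#' @param path Output path; when `NULL` the SBML text is returned.
#' @param provenance_notes When `TRUE`, writes tool name/version/date into
#'   the model `notes` element.  Off by default: the standard annotation
#'   syntax has no slot for stating which procedure added an annotation, so
#'   by default the output model contains no tool provenance and the audit
#'   trail lives in the pipeline's delta report instead.
#' @return SBML text (invisibly when written to a file).
#' @export
write_sbml <- function(model, path = NULL, provenance_notes = FALSE) {
  stopifnot(inherits(model, "sbml_model"))
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" level="%d" version="%d">',
            sprintf(SBML_L2_NS, model$version), model$level, model$version),
    paste0("  <model", fmt_attr("id", model$id), fmt_attr("name", model$name), ">")
  )
  if (provenance_notes) {
    out <- c(out,
      "    <notes>",
      '      <body xmlns="http://www.w3.org/1999/xhtml">',
      sprintf("        <p>Annotations added by rbmed %s on %s.</p>",
              as.character(utils::packageVersion("rbmed")), format(Sys.Date())),
      "      </body>",
      "    </notes>")
  }
  if (length(model$compartments)) {
    out <- c(out, "    <listOfCompartments>")
    for (cp in model$compartments) {
      out <- c(out, paste0("      <compartment", fmt_attr("id", cp$id),
                           fmt_attr("name", cp$name), fmt_attr("size", cp$size), "/>"))
    }
    out <- c(out, "    </listOfCompartments>")
  }
  if (length(model$species)) {
    out <- c(out, "    <listOfSpecies>")
    for (s in model$species) {
      metaid <- s$metaid
      if (is_blank(metaid) && length(s$annotations)) metaid <- paste0("meta_", s$id)
      head <- paste0("      <species", fmt_attr("id", s$id),
                     fmt_attr("metaid", metaid), fmt_attr("name", s$name),
                     fmt_attr("compartment", s$compartment),
                     fmt_attr("initialAmount", s$initialAmount),
                     fmt_attr("sboTerm", s$sboTerm))
      if (length(s$annotations)) {
        out <- c(out, paste0(head, ">"),
                 annotation_lines(metaid, s$annotations, 8L),
                 "      </species>")
      } else {
        out <- c(out, paste0(head, "/>"))
      }
    }
    out <- c(out, "    </listOfSpecies>")
  }
  if (length(model$reactions)) {
    out <- c(out, "    <listOfReactions>")
    for (r in model$reactions) {
      metaid <- r$metaid
      if (is_blank(metaid) && length(r$annotations)) metaid <- paste0("meta_", r$id)
      head <- paste0("      <reaction", fmt_attr("id", r$id),
                     fmt_attr("metaid", metaid), fmt_attr("name", r$name),
                     sprintf(' reversible="%s"', if (isTRUE(r$reversible)) "true" else "false"))
      body <- character()
      if (length(r$annotations)) {
        body <- c(body, annotation_lines(metaid, r$annotations, 8L))
      }
      if (length(r$reactants)) {
        body <- c(body, "        <listOfReactants>",
                  sprintf('          <speciesReference species="%s"/>', r$reactants),
                  "        </listOfReactants>")
      }
      if (length(r$products)) {
        body <- c(body, "        <listOfProducts>",
                  sprintf('          <speciesReference species="%s"/>', r$products),
                  "        </listOfProducts>")
      }
      if (length(r$modifiers)) {
        body <- c(body, "        <listOfModifiers>",
                  sprintf('          <modifierSpeciesReference species="%s"/>', r$modifiers),
                  "        </listOfModifiers>")
      }
      if (length(body)) {
        out <- c(out, paste0(head, ">"), body, "      </reaction>")
      } else {
        out <- c(out, paste0(head, "/>"))
      }
    }
    out <- c(out, "    </listOfReactions>")
  }
  out <- c(out, "  </model>", "</sbml>")
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(text, path, sep = "")
  invisible(text)
}

#' Structurally validate an SBML model
#'
#' Checks identifier well-formedness and uniqueness, compartment and species
#' reference integrity, that every reaction has at least one species
#' reference, the 7-digit `SBO:` term pattern, known biology qualifiers and
#' MIRIAM-shaped annotation URIs.
#'
#' @param model An `sbml_model` (or a path, which is read first).
#' @return `list(valid = <logical>, errors = <character>)`.
#' @export
validate_sbml <- function(model) {
  if (is.character(model)) model <- read_sbml(model)
  errors <- character()
  note <- function(...) errors <<- c(errors, sprintf(...))
  sid_ok <- function(x) grepl("^[A-Za-z_][A-Za-z0-9_]*$", x)
  cids <- vapply(model$compartments, function(cp) cp$id %||% NA_character_, character(1))
  sids <- species_ids(model)
  rids <- reaction_ids(model)
  all_ids <- c(cids, sids, rids[!is.na(rids)])
  if (anyDuplicated(all_ids)) {
    note("duplicate identifiers: %s", paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  }
  for (x in all_ids) if (!sid_ok(x)) note("malformed identifier '%s'", x)
  for (s in model$species) {
    if (is_blank(s$compartment) || !s$compartment %in% cids) {
      note("species '%s' references unknown compartment '%s'", s$id, s$compartment %||% "")
    }
    if (!is_blank(s$sboTerm) && !grepl("^SBO:[0-9]{7}$", s$sboTerm)) {
      note("species '%s' has malformed sboTerm '%s'", s$id, s$sboTerm)
    }
    for (a in s$annotations) {
      if (!a$qualifier %in% MIRIAM_QUALIFIERS) {
        note("species '%s' uses unknown qualifier '%s'", s$id, a$qualifier)
      }
      if (!valid_miriam_uri(a$uri)) {
        note("species '%s' has non-MIRIAM annotation URI '%s'", s$id, a$uri)
      }
    }
  }
  for (r in model$reactions) {
    involved <- reaction_species(r)
    if (!length(involved)) {
      note("reaction '%s' has no species references", r$id %||% "?")
    }
    for (sp in involved) {
      if (!sp %in% sids) note("reaction '%s' references unknown species '%s'", r$id %||% "?", sp)
    }
  }
  list(valid = !length(errors), errors = errors)
}
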
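# Format-aware readers producing populated syntactic ontologies for the
# three general data inputs: UniProtKB-style XML, PSI-MI 1.0-style
# interaction XML, and BioPAX level-2-style RDF/XML (parsed natively from
# RDF, since BioPAX is already an ontology).  The UniProt and PSI-MIF readers
# are thin specializations of the generic XML converter with a *pinned*
# schema, so class names are stable anchors for rule atoms no matter which
# instance documents are loaded.  Readers never merge records across
# sources; reconciliation is a separate, later stage.

# Exemplar documents fixing the dialect vocabulary (and hence the pinned
# schemas).  The subsets cover exactly the structures the integration rules
# touch.
UNIPROT_TEMPLATE <- '<uniprot>
  <entry>
    <accession>P00000</accession>
    <name>TMPL_YEAST</name>
    <protein>
      <recommendedName><fullName>template</fullName></recommendedName>
      <alternativeName><fullName>template</fullName></alternativeName>
    </protein>
    <gene><name type="primary">TMPL</name></gene>
    <organism>
      <name type="scientific">template</name>
      <dbReference type="NCBI Taxonomy" id="1"/>
    </organism>
    <dbReference type="TemplateDb" id="T1"/>
    <comment type="function"><text>template</text></comment>
    <comment type="subcellular location">
      <subcellularLocation><location>template</location></subcellularLocation>
    </comment>
  </entry>
</uniprot>'

PSIMIF_TEMPLATE <- '<entrySet>
  <entry>
    <interactorList>
      <proteinInteractor id="tmpl">
        <names><shortLabel>TMPL</shortLabel><fullName>template</fullName></names>
        <xref>
          <primaryRef db="uniprotkb" id="P00000"/>
          <secondaryRef db="templatedb" id="T1"/>
        </xref>
        <organism ncbiTaxId="1"/>
      </proteinInteractor>
    </interactorList>
    <interactionList>
      <interaction>
        <names><shortLabel>template</shortLabel></names>
        <participantList>
          <proteinParticipant><proteinInteractorRef ref="tmpl"/></proteinParticipant>
        </participantList>
      </interaction>
    </interactionList>
  </entry>
</entrySet>'

uniprot_convention <- function() xml_mapping_convention(prefix = "up:")
psimif_convention <- function() xml_mapping_convention(prefix = "psi:")

#' Read UniProtKB-style XML into a syntactic ontology
#'
#' Entry instances expose primary and secondary accessions, protein names
#' and synonyms, the organism taxon id, entry-level cross-references and
#' subcellular-location text, all under `up:`-prefixed classes/properties.
#' Entries lacking a primary accession are skipped with a warning.
#'
#' @param files Character vector of file paths.
#' @param source_label Provenance label stamped on every instance.
#' @return A populated `InstanceGraph`.
#' @export
read_uniprot <- function(files, source_label = "UniProtKB") {
  conv <- uniprot_convention()
  g <- derive_schema(UNIPROT_TEMPLATE, conv)
  for (i in seq_along(files)) {
    doc <- read_xml_doc(files[[i]])
    for (entry in xml2::xml_find_all(doc, ".//*[local-name()='entry']")) {
      accs <- xml2::xml_find_all(entry, "./*[local-name()='accession']")
      if (!length(accs) || !nzchar(trimws(xml2::xml_text(accs[[1]])))) {
        nm <- xml2::xml_text(
          xml2::xml_find_first(entry, "./*[local-name()='name']"))
        warning(sprintf("skipping entry '%s' in '%s': no primary accession",
                        if (is.na(nm)) "<unnamed>" else nm, files[[i]]))
        xml2::xml_remove(entry)
      }
    }
    ns <- if (length(files) == 1L) "uniprot" else sprintf("uniprot%d", i)
    populate(doc, g, conv, source_label = source_label,
             mode = "strict", namespace = ns)
  }
  g
}

#' Read PSI-MI 1.0-style interaction XML into a syntactic ontology
#'
#' Produces `psi:ProteinInteractor` and `psi:Interaction` instances (plus the
#' participant plumbing connecting them).  An interaction whose participant
#' references an undeclared interactor id is an integrity error.
#'
#' @inheritParams read_uniprot
#' @return A populated `InstanceGraph`.
#' @export
read_psimif <- function(files, source_label = "BioGRID") {
  conv <- psimif_convention()
  g <- derive_schema(PSIMIF_TEMPLATE, conv)
  for (i in seq_along(files)) {
    ns <- if (length(files) == 1L) "biogrid" else sprintf("biogrid%d", i)
    populate(files[[i]], g, conv, source_label = source_label,
             mode = "strict", namespace = ns)
  }
  declared <- unlist(lapply(instances_of(g, "psi:ProteinInteractor"),
                            function(id) assertion_values(g, id, "psi:hasId")))
  for (id in instances_of(g, "psi:ProteinInteractorRef")) {
    for (r in assertion_values(g, id, "psi:hasRef")) {
      if (!r %in% declared) {
        stop(sprintf("interaction participant references undeclared interactor id '%s'", r))
      }
    }
  }
  g
}

# ---------------------------------------------------------------------------
# BioPAX (native RDF/XML)

BIOPAX_KNOWN_CLASSES <- c(
  "protein", "physicalEntity", "physicalEntityParticipant",
  "sequenceParticipant", "interaction", "physicalInteraction",
  "unificationXref", "relationshipXref", "xref", "bioSource",
  "openControlledVocabulary", "entity"
)

biopax_schema <- function() {
  g <- instance_graph()
  add_class(g, "bp:entity")
  add_class(g, "bp:physicalEntity", "bp:entity")
  add_class(g, "bp:protein", "bp:physicalEntity")
  add_class(g, "bp:interaction", "bp:entity")
  add_class(g, "bp:physicalInteraction", "bp:interaction")
  add_class(g, "bp:physicalEntityParticipant")
  add_class(g, "bp:sequenceParticipant", "bp:physicalEntityParticipant")
  add_class(g, "bp:xref")
  add_class(g, "bp:unificationXref", "bp:xref")
  add_class(g, "bp:relationshipXref", "bp:xref")
  add_class(g, "bp:bioSource")
  add_class(g, "bp:openControlledVocabulary")
  for (p in c("bp:NAME", "bp:SHORT-NAME", "bp:SYNONYMS", "bp:DB", "bp:ID",
              "bp:COMMENT")) {
    add_property(g, p, "data")
  }
  for (p in c("bp:XREF", "bp:ORGANISM", "bp:PARTICIPANTS", "bp:PHYSICAL-ENTITY",
              "bp:TAXON-XREF")) {
    add_property(g, p, "object")
  }
  g
}

#' Read a BioPAX level-2-style RDF/XML document
#'
#' BioPAX is already an ontology, so no schema induction happens: resources
#' become instances of `bp:`-prefixed classes mirroring the BioPAX class
#' names, preserving the physicalEntity / physicalEntityParticipant
#' dichotomy (the entity versus its participant occurrences).  The fixture
#' dialect is flat RDF/XML: every resource is a direct child of `rdf:RDF`
#' carrying `rdf:ID`, with `rdf:resource` references between resources.
#' Resources of unknown BioPAX class are kept as generic `bp:entity` with a
#' warning.
#'
#' @param file RDF/XML file path.
#' @param source_label Provenance label stamped on every instance.
#' @return A populated `InstanceGraph`.
#' @export
read_biopax <- function(file, source_label = "PathwayCommons") {
  doc <- tryCatch(xml2::read_xml(file), error = function(e) {
    stop(sprintf("RDF parse failure in '%s': %s", file, conditionMessage(e)))
  })
  root <- xml2::xml_root(doc)
  if (local_tag(root) != "RDF") {
    stop(sprintf("RDF parse failure in '%s': root element is '%s', expected rdf:RDF",
                 file, local_tag(root)))
  }
  g <- biopax_schema()
  ns <- "pathwaycommons"
  nodes <- element_children(root)
  node_attr <- xml_attr_local
  resource_id <- function(node) {
    rid <- node_attr(node, "ID")
    if (is.na(rid)) rid <- sub("^#", "", node_attr(node, "about"))
    rid
  }
  # pass 1: declare instances
  kept <- list()
  for (node in nodes) {
    tag <- local_tag(node)
    if (tag == "Ontology") next  # owl:Ontology header, no instance
    rid <- resource_id(node)
    if (is.na(rid) || !nzchar(rid)) {
      stop(sprintf("RDF parse failure in '%s': resource of class '%s' lacks rdf:ID/rdf:about",
                   file, tag))
    }
    cls <- paste0("bp:", tag)
    if (!tag %in% BIOPAX_KNOWN_CLASSES) {
      warning(sprintf("unknown BioPAX class '%s' for resource '%s'; kept as generic bp:entity",
                      tag, rid))
      cls <- "bp:entity"
    }
    add_instance(g, paste0(ns, "#", rid), cls, source_label)
    kept[[length(kept) + 1L]] <- list(node = node, id = paste0(ns, "#", rid))
  }
  # pass 2: assertions (references may point forward)
  for (item in kept) {
    for (child in element_children(item$node)) {
      pname <- paste0("bp:", local_tag(child))
      res <- node_attr(child, "resource")
      if (!is.na(res)) {
        if (is.null(g$properties[[pname]])) add_property(g, pname, "object")
        add_assertion(g, item$id, pname, ref(paste0(ns, "#", sub("^#", "", res))))
      } else {
        txt <- trimws(xml2::xml_text(child))
        if (!nzchar(txt)) next
        if (is.null(g$properties[[pname]])) add_property(g, pname, "data")
        add_assertion(g, item$id, pname, lit(txt))
      }
    }
  }
  validate_graph(g)
  g
}

#' Read a described source into a syntactic ontology
#'
#' Dispatches on the descriptor's format: `uniprot-xml`, `psi-mif` or
#' `biopax-rdf`.  (SBML models are read by [read_sbml()]: the model is both
#' an input and the annotation target.)
#'
#' @param descriptor `list(name=, format=, path=)`; `path` may be a vector
#'   for the XML formats.
#' @return A populated `InstanceGraph` whose instances carry the
#'   descriptor's name as provenance label.
#' @export
read_source <- function(descriptor) {
  stopifnot(is.list(descriptor), !is.null(descriptor$format), !is.null(descriptor$path))
  name <- descriptor$name %||% descriptor$format
  switch(descriptor$format,
    "uniprot-xml" = read_uniprot(descriptor$path, source_label = name),
    "psi-mif"     = read_psimif(descriptor$path, source_label = name),
    "biopax-rdf"  = read_biopax(descriptor$path, source_label = name),
    stop(sprintf("unknown source format '%s'", descriptor$format))
  )
}
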
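# Deterministic synthetic corpus emulating the integration scenario: a
# UniProtKB-style entry set, a BioGRID-style PSI-MIF interaction file, a
# Pathway Commons-style BioPAX document, a toy SBML model of the RAD9
# checkpoint module (a synthetic stand-in for the published telomere
# uncapping model, constrained to the documented facts: two RAD9 species,
# four RAD9 interactions, named and placeholder partners), and the rule /
# schema / registry files driving the pipeline.  The default corpus uses no
# randomness, so regeneration is checksum-identical.

YEAST_TAXON <- "4932"
HUMAN_TAXON <- "9606"

# protein roster shared by the generators (ids, names, cross-references)
corpus_roster <- function() {
  list(
    rad9 = list(
      accessions = c("P14737", "D6VQV2"), entry = "RAD9_YEAST",
      full = "DNA damage-dependent checkpoint protein RAD9",
      gene = "RAD9", gene_syns = character(), taxon = YEAST_TAXON,
      xrefs = list(c("IntAct", "EBI-14930"), c("SGD", "S000002625")),
      fn = "Mediator of the DNA damage checkpoint; adaptor for checkpoint signalling.",
      loc = "Nucleus"),
    rad53 = list(
      accessions = "P22216", entry = "RAD53_YEAST",
      full = "Serine/threonine-protein kinase RAD53",
      gene = "RAD53", gene_syns = "SPK1", taxon = YEAST_TAXON,
      xrefs = list(c("SGD", "S000005941"), c("EMBL", "X12345")),
      fn = NULL, loc = "Nucleus"),
    chk1 = list(
      accessions = "P38147", entry = "CHK1_YEAST",
      full = "Serine/threonine-protein kinase CHK1",
      gene = "CHK1", gene_syns = character(), taxon = YEAST_TAXON,
      xrefs = list(c("SGD", "S000000371")),
      fn = NULL, loc = "Nucleus"),
    mec1 = list(
      accessions = "P38111", entry = "MEC1_YEAST",
      full = "Serine/threonine-protein kinase MEC1",
      gene = "MEC1", gene_syns = c("ESR1", "SAD3"), taxon = YEAST_TAXON,
      xrefs = list(c("SGD", "S000002670")),
      fn = "Serine/threonine-protein kinase which phosphorylates RAD9 in response to DNA damage, activating the checkpoint response.",
      loc = "Nucleus"),
    rad17 = list(
      accessions = "P48581", entry = "RAD17_YEAST",
      full = "DNA damage checkpoint control protein RAD17",
      gene = "RAD17", gene_syns = character(), taxon = YEAST_TAXON,
      xrefs = list(c("SGD", "S000005602")),
      fn = NULL, loc = "Nucleus"),
    decoy_human_rad9 = list(
      accessions = "Q99999", entry = "RAD9A_HUMAN",
      full = "Cell cycle checkpoint control protein RAD9A",
      gene = "RAD9A", gene_syns = "RAD9", taxon = HUMAN_TAXON,
      xrefs = list(c("IntAct", "EBI-99999")),
      fn = NULL, loc = "Nucleus", decoy = TRUE)
  )
}

uniprot_entry_xml <- function(p) {
  x <- c("  <entry>",
         sprintf("    <accession>%s</accession>", p$accessions),
         sprintf("    <name>%s</name>", p$entry),
         "    <protein>",
         sprintf("      <recommendedName><fullName>%s</fullName></recommendedName>",
                 xml_escape(p$full)),
         "    </protein>",
         "    <gene>",
         sprintf('      <name type="primary">%s</name>', p$gene))
  if (length(p$gene_syns)) {
    x <- c(x, sprintf('      <name type="synonym">%s</name>', p$gene_syns))
  }
  x <- c(x, "    </gene>",
         "    <organism>",
         sprintf('      <dbReference type="NCBI Taxonomy" id="%s"/>', p$taxon),
         "    </organism>")
  for (xr in p$xrefs) {
    x <- c(x, sprintf('    <dbReference type="%s" id="%s"/>', xr[[1]], xr[[2]]))
  }
  if (!is.null(p$fn)) {
    x <- c(x, '    <comment type="function">',
           sprintf("      <text>%s</text>", xml_escape(p$fn)),
           "    </comment>")
  }
  if (!is.null(p$loc)) {
    x <- c(x, '    <comment type="subcellular location">',
           "      <subcellularLocation>",
           sprintf("        <location>%s</location>", p$loc),
           "      </subcellularLocation>",
           "    </comment>")
  }
  c(x, "  </entry>")
}

write_uniprot_fixture <- function(roster, path, include_decoys) {
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>', "<uniprot>")
  for (p in roster) {
    if (isTRUE(p$decoy) && !include_decoys) next
    lines <- c(lines, uniprot_entry_xml(p))
  }
  writeLines(c(lines, "</uniprot>"), path)
}

psimif_interactor_xml <- function(id, label, full, acc, taxon) {
  c(sprintf('      <proteinInteractor id="%s">', id),
    "        <names>",
    sprintf("          <shortLabel>%s</shortLabel>", label),
    sprintf("          <fullName>%s</fullName>", xml_escape(full)),
    "        </names>",
    "        <xref>",
    sprintf('          <primaryRef db="uniprotkb" id="%s"/>', acc),
    "        </xref>",
    sprintf('        <organism ncbiTaxId="%s"/>', taxon),
    "      </proteinInteractor>")
}

psimif_interaction_xml <- function(label, refs) {
  c("      <interaction>",
    "        <names>",
    sprintf("          <shortLabel>%s</shortLabel>", label),
    "        </names>",
    "        <participantList>",
    unlist(lapply(refs, function(r) c(
      "          <proteinParticipant>",
      sprintf('            <proteinInteractorRef ref="%s"/>', r),
      "          </proteinParticipant>"))),
    "        </participantList>",
    "      </interaction>")
}

write_psimif_fixture <- function(roster, path, include_decoys, noise = NULL) {
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             "<entrySet>", "  <entry>", "    <interactorList>")
  mk <- function(key, id) {
    p <- roster[[key]]
    psimif_interactor_xml(id, p$gene, p$full, p$accessions[[1]], p$taxon)
  }
  lines <- c(lines,
             mk("rad9", "bgr_rad9"), mk("rad53", "bgr_rad53"),
             mk("mec1", "bgr_mec1"), mk("rad17", "bgr_rad17"))
  if (include_decoys) {
    lines <- c(lines, psimif_interactor_xml(
      "bgr_dbp1", "DBP1", "Decoy binding protein 1", "P99901", YEAST_TAXON))
  }
  for (n in noise %||% list()) {
    lines <- c(lines, psimif_interactor_xml(
      n$id, n$label, paste("Synthetic noise protein", n$label), n$acc, YEAST_TAXON))
  }
  lines <- c(lines, "    </interactorList>", "    <interactionList>",
             psimif_interaction_xml("RAD9-RAD53", c("bgr_rad9", "bgr_rad53")),
             psimif_interaction_xml("RAD9-MEC1", c("bgr_rad9", "bgr_mec1")),
             psimif_interaction_xml("RAD9-RAD17", c("bgr_rad9", "bgr_rad17")))
  if (include_decoys) {
    lines <- c(lines, psimif_interaction_xml("DBP1-RAD53", c("bgr_dbp1", "bgr_rad53")))
  }
  for (n in noise %||% list()) {
    lines <- c(lines, psimif_interaction_xml(
      paste0(n$label, "-RAD53"), c(n$id, "bgr_rad53")))
  }
  writeLines(c(lines, "    </interactionList>", "  </entry>", "</entrySet>"), path)
}

write_biopax_fixture <- function(roster, path) {
  bp_protein <- function(rid, p, extra_xrefs = character()) {
    c(sprintf('  <bp:protein rdf:ID="%s">', rid),
      sprintf("    <bp:NAME>%s</bp:NAME>", xml_escape(p$full)),
      sprintf("    <bp:SHORT-NAME>%s</bp:SHORT-NAME>", p$gene),
      sprintf('    <bp:XREF rdf:resource="#%s_uniprot"/>', rid),
      sprintf('    <bp:XREF rdf:resource="#%s"/>', extra_xrefs),
      '    <bp:ORGANISM rdf:resource="#biosource_yeast"/>',
      "  </bp:protein>",
      sprintf('  <bp:unificationXref rdf:ID="%s_uniprot">', rid),
      "    <bp:DB>UniProtKB</bp:DB>",
      sprintf("    <bp:ID>%s</bp:ID>", p$accessions[[1]]),
      "  </bp:unificationXref>")
  }
  rel_xref <- function(rid, id) {
    c(sprintf('  <bp:relationshipXref rdf:ID="%s">', rid),
      "    <bp:DB>Pathway Commons</bp:DB>",
      sprintf("    <bp:ID>%s</bp:ID>", id),
      "  </bp:relationshipXref>")
  }
  pep <- function(rid, protein) {
    c(sprintf('  <bp:physicalEntityParticipant rdf:ID="%s">', rid),
      sprintf('    <bp:PHYSICAL-ENTITY rdf:resource="#%s"/>', protein),
      "  </bp:physicalEntityParticipant>")
  }
  interaction <- function(rid, name, peps) {
    c(sprintf('  <bp:physicalInteraction rdf:ID="%s">', rid),
      sprintf("    <bp:NAME>%s</bp:NAME>", name),
      sprintf('    <bp:PARTICIPANTS rdf:resource="#%s"/>', peps),
      "  </bp:physicalInteraction>")
  }
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"',
           ' xmlns:bp="http://www.biopax.org/release/biopax-level2.owl#">'),
    bp_protein("protein_rad9", roster$rad9,
               c("xref_rad9_pc_record", "xref_rad9_pc_pathway")),
    rel_xref("xref_rad9_pc_record", "CPATH-80001"),
    rel_xref("xref_rad9_pc_pathway", "CPATH-90001"),
    bp_protein("protein_rad53", roster$rad53),
    bp_protein("protein_chk1", roster$chk1),
    pep("pep_rad9_a", "protein_rad9"),
    pep("pep_rad53_a", "protein_rad53"),
    pep("pep_rad9_b", "protein_rad9"),
    pep("pep_chk1_a", "protein_chk1"),
    interaction("int_rad9_rad53", "RAD9 - RAD53 interaction",
                c("pep_rad9_a", "pep_rad53_a")),
    interaction("int_rad9_chk1", "RAD9 - CHK1 interaction",
                c("pep_rad9_b", "pep_chk1_a")),
    '  <bp:bioSource rdf:ID="biosource_yeast">',
    "    <bp:NAME>Saccharomyces cerevisiae</bp:NAME>",
    '    <bp:TAXON-XREF rdf:resource="#xref_taxon_yeast"/>',
    "  </bp:bioSource>",
    '  <bp:unificationXref rdf:ID="xref_taxon_yeast">',
    "    <bp:DB>NCBI Taxonomy</bp:DB>",
    sprintf("    <bp:ID>%s</bp:ID>", YEAST_TAXON),
    "  </bp:unificationXref>",
    "</rdf:RDF>")
  writeLines(lines, path)
}

toy_model_species <- function() {
  rad9_ann <- list(list(qualifier = "is", uri = "urn:miriam:uniprot:P14737"))
  mk <- function(id, name, ann = list()) {
    list(id = id, metaid = paste0("meta_", id), name = name,
         compartment = "nucleus", initialAmount = "0", sboTerm = NULL,
         annotations = ann)
  }
  list(mk("Rad9_inactive", "Rad9 inactive", rad9_ann),
       mk("Rad9_active", "Rad9 active", rad9_ann),
       mk("Rad53", "Rad53"), mk("Rad53_active", "Rad53 active"),
       mk("Chk1", "Chk1"), mk("Chk1_active", "Chk1 active"),
       mk("Rad9Kin", "Rad9Kin"), mk("ExoX", "ExoX"),
       mk("Mec1", "Mec1"), mk("Rad17", "Rad17"))
}

toy_model_reactions <- function() {
  mk <- function(id, name, reactants, products, modifiers) {
    list(id = id, metaid = NULL, name = name, reversible = FALSE,
         reactants = reactants, products = products, modifiers = modifiers,
         annotations = list())
  }
  list(
    mk("rad9_activation", "Rad9 activation by Rad9Kin",
       "Rad9_inactive", "Rad9_active", "Rad9Kin"),
    mk("rad53_activation_by_rad9", "Rad53 activation by Rad9",
       "Rad53", "Rad53_active", "Rad9_active"),
    mk("chk1_activation_by_rad9", "Chk1 activation by Rad9",
       "Chk1", "Chk1_active", "Rad9_active"),
    mk("rad9_degradation_by_exox", "Rad9 degradation by ExoX",
       "Rad9_active", character(), "ExoX"),
    mk("rad53_activation_by_mec1", "Rad53 activation by Mec1",
       "Rad53", "Rad53_active", "Mec1")
  )
}

toy_model <- function() {
  structure(list(
    level = 2L, version = 4L,
    id = "toy_checkpoint_model",
    name = "Synthetic RAD9 checkpoint toy model",
    compartments = list(list(id = "nucleus", name = "Nucleus", size = "1")),
    species = toy_model_species(),
    reactions = toy_model_reactions()
  ), class = "sbml_model")
}

copy_shipped <- function(rel, dir) {
  src <- system.file(rel, package = "rbmed")
  if (!nzchar(src)) stop(sprintf("shipped file '%s' not found", rel))
  dest <- file.path(dir, basename(rel))
  file.copy(src, dest, overwrite = TRUE)
  basename(rel)
}

#' Generate the synthetic fixture corpus
#'
#' Writes the full input set of the integration pipeline into a directory:
#' the three source files, the toy SBML model (labelled synthetic), the core
#' schema, rule files, MIRIAM registry, export map and a ready-to-run
#' `pipeline.yaml`, plus a `manifest.yaml` with per-file checksums and the
#' protein/interaction rosters.  The default corpus is fully deterministic;
#' `seed` only controls optional extra noise interactors appended to the
#' interaction file (never sharing a reconciliation key with roster
#' proteins).
#'
#' @param dir Output directory (created if missing).
#' @param include_decoys Include the human RAD9 homolog entry (removed only
#'   by organism restriction) and the DBP1 decoy interactor (filtered only
#'   by the classification rules).
#' @param noise Number of extra synthetic noise interactors; requires
#'   `seed` when positive.
#' @param seed Integer seed for the optional noise records.
#' @return A `CorpusManifest` (invisibly); also written as
#'   `manifest.yaml`.
#' @export
generate_corpus <- function(dir, include_decoys = TRUE, noise = 0L, seed = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!dir.exists(dir)) stop(sprintf("cannot create corpus directory '%s'", dir))
  roster <- corpus_roster()
  noise_records <- list()
  if (noise > 0L) {
    if (is.null(seed)) stop("noise records require a seed")
    set.seed(seed)
    for (i in seq_len(noise)) {
      label <- paste0("NSE", i, paste(sample(LETTERS, 2L), collapse = ""))
      noise_records[[i]] <- list(id = paste0("bgr_noise", i), label = label,
                                 acc = sprintf("P9%04d", sample.int(9999L, 1L)))
    }
  }
  files <- c(
    uniprot = "uniprot-entries-synthetic.xml",
    psimif = "biogrid-psimif-synthetic.xml",
    biopax = "pathwaycommons-biopax-synthetic.owl",
    model = "toy-model-synthetic.xml"
  )
  write_uniprot_fixture(roster, file.path(dir, files[["uniprot"]]), include_decoys)
  write_psimif_fixture(roster, file.path(dir, files[["psimif"]]), include_decoys,
                       noise_records)
  write_biopax_fixture(roster, file.path(dir, files[["biopax"]]))
  write_sbml(toy_model(), file.path(dir, files[["model"]]))
  shipped <- c(
    copy_shipped("schema/core_schema.yaml", dir),
    copy_shipped("rules/import_uniprot.rules", dir),
    copy_shipped("rules/import_psimif.rules", dir),
    copy_shipped("rules/import_biopax.rules", dir),
    copy_shipped("rules/classify_proteins.rules", dir),
    copy_shipped("rules/query_interactions.rules", dir),
    copy_shipped("extdata/miriam_registry.yaml", dir),
    copy_shipped("extdata/export_map.yaml", dir)
  )
  config <- list(
    taxon = YEAST_TAXON,
    sources = list(
      list(name = "UniProtKB", format = "uniprot-xml", path = files[["uniprot"]]),
      list(name = "BioGRID", format = "psi-mif", path = files[["psimif"]]),
      list(name = "PathwayCommons", format = "biopax-rdf", path = files[["biopax"]])
    ),
    model = files[["model"]],
    core_schema = "core_schema.yaml",
    rules = list(
      import = c("import_uniprot.rules", "import_psimif.rules",
                 "import_biopax.rules"),
      classification = "classify_proteins.rules",
      query = "query_interactions.rules"
    ),
    interaction_classes = c("tuo:Rad9Rad53Interaction", "tuo:Rad9Chk1Interaction",
                            "tuo:Rad9Mec1Interaction", "tuo:Rad9Rad17Interaction"),
    partner_classes = c("tuo:Rad53", "tuo:Chk1", "tuo:Mec1", "tuo:Rad17"),
    focus_class = "tuo:Rad9",
    miriam_registry = "miriam_registry.yaml",
    export_map = "export_map.yaml",
    reconciliation_keys = c("accession", "name_taxon"),
    output = list(model = "annotated-model.xml", delta = "delta.json",
                  core_graph = "core-graph.ttl"),
    flags = list(provenance_notes = FALSE)
  )
  yaml::write_yaml(config, file.path(dir, "pipeline.yaml"))
  all_files <- c(unname(files), shipped, "pipeline.yaml")
  sums <- tools::md5sum(file.path(dir, all_files))
  names(sums) <- all_files
  manifest <- list(
    taxon = YEAST_TAXON,
    include_decoys = include_decoys,
    noise = noise,
    accessions = vapply(roster[!vapply(roster, function(p) isTRUE(p$decoy), logical(1))],
                        function(p) p$accessions[[1]], character(1)),
    decoy_accessions = if (include_decoys) {
      c(vapply(roster[vapply(roster, function(p) isTRUE(p$decoy), logical(1))],
               function(p) p$accessions[[1]], character(1)),
        dbp1 = "P99901")
    } else character(),
    interactions = list(
      BioGRID = c("RAD9-RAD53", "RAD9-MEC1", "RAD9-RAD17"),
      PathwayCommons = c("RAD9-RAD53", "RAD9-CHK1")
    ),
    files = as.list(sums)
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(structure(manifest, class = "CorpusManifest"))
}
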
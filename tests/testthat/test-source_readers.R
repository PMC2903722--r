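test_that("the UniProt reader exposes accessions and skips accession-less entries", {
  d <- corpus_dir()
  g <- read_uniprot(file.path(d, "uniprot-entries-synthetic.xml"))
  entries <- instances_of(g, "up:Entry")
  expect_length(entries, 6L)  # 5 roster proteins + 1 human decoy homolog

  # primary accessions recoverable from each entry (scan oracle)
  accs <- vapply(entries, function(e) {
    acc_inst <- assertion_values(g, e, "up:hasAccession")[[1]]
    assertion_values(g, acc_inst, "up:hasValue")[[1]]
  }, character(1))
  expect_setequal(unname(accs),
                  c("P14737", "P22216", "P38147", "P38111", "P48581", "Q99999"))
  expect_true(all(vapply(entries, function(e) {
    identical(g$instances[[e]]$source, "UniProtKB")
  }, logical(1))))

  # entry with no primary accession is skipped with a record-level warning
  broken <- tempfile(fileext = ".xml")
  writeLines('<uniprot>
    <entry><name>NOACC_YEAST</name></entry>
    <entry><accession>P00001</accession><name>OK_YEAST</name></entry>
  </uniprot>', broken)
  expect_warning(g2 <- read_uniprot(broken), "no primary accession")
  expect_length(instances_of(g2, "up:Entry"), 1L)

  # zero entries is fine
  empty <- tempfile(fileext = ".xml")
  writeLines("<uniprot/>", empty)
  expect_length(instances_of(read_uniprot(empty), "up:Entry"), 0L)
})

test_that("the PSI-MIF reader links interactions to declared interactors", {
  d <- corpus_dir()
  f <- file.path(d, "biogrid-psimif-synthetic.xml")
  g <- read_psimif(f)

  doc <- xml2::read_xml(f)
  n_int <- length(xml2::xml_find_all(doc, "//*[local-name()='interaction']"))
  expect_length(instances_of(g, "psi:Interaction"), n_int)

  # short labels of each interaction's interactors, resolved through refs
  interactor_label <- function(iid) {
    nm <- assertion_values(g, iid, "psi:hasNames")[[1]]
    sl <- assertion_values(g, nm, "psi:hasShortLabel")[[1]]
    assertion_values(g, sl, "psi:hasValue")[[1]]
  }
  id_index <- vapply(instances_of(g, "psi:ProteinInteractor"),
                     function(i) assertion_values(g, i, "psi:hasId")[[1]],
                     character(1))
  partners <- lapply(instances_of(g, "psi:Interaction"), function(x) {
    pl <- assertion_values(g, x, "psi:hasParticipantList")[[1]]
    parts <- assertion_values(g, pl, "psi:hasProteinParticipant")
    sort(vapply(parts, function(p) {
      r <- assertion_values(g, p, "psi:hasProteinInteractorRef")[[1]]
      rid <- assertion_values(g, r, "psi:hasRef")[[1]]
      interactor_label(names(id_index)[id_index == rid])
    }, character(1)))
  })
  expect_true(any(vapply(partners, function(p) setequal(p, c("RAD9", "RAD53")), logical(1))))
  expect_true(any(vapply(partners, function(p) setequal(p, c("RAD9", "MEC1")), logical(1))))
  expect_true(any(vapply(partners, function(p) setequal(p, c("RAD9", "RAD17")), logical(1))))
  expect_false(any(vapply(partners, function(p) "CHK1" %in% p, logical(1))))

  # interactors without interactions are fine
  only <- tempfile(fileext = ".xml")
  writeLines('<entrySet><entry><interactorList>
    <proteinInteractor id="x1">
      <names><shortLabel>X1</shortLabel></names>
      <xref><primaryRef db="uniprotkb" id="P00001"/></xref>
      <organism ncbiTaxId="4932"/>
    </proteinInteractor>
  </interactorList></entry></entrySet>', only)
  g2 <- read_psimif(only)
  expect_length(instances_of(g2, "psi:ProteinInteractor"), 1L)
  expect_length(instances_of(g2, "psi:Interaction"), 0L)

  # undeclared interactor reference is an integrity error naming the id
  bad <- tempfile(fileext = ".xml")
  writeLines('<entrySet><entry>
    <interactorList>
      <proteinInteractor id="x1">
        <names><shortLabel>X1</shortLabel></names>
        <xref><primaryRef db="uniprotkb" id="P00001"/></xref>
        <organism ncbiTaxId="4932"/>
      </proteinInteractor>
    </interactorList>
    <interactionList><interaction>
      <names><shortLabel>broken</shortLabel></names>
      <participantList>
        <proteinParticipant><proteinInteractorRef ref="ghost"/></proteinParticipant>
        <proteinParticipant><proteinInteractorRef ref="x1"/></proteinParticipant>
      </participantList>
    </interaction></interactionList>
  </entry></entrySet>', bad)
  expect_error(read_psimif(bad), "undeclared interactor id 'ghost'")
})

test_that("the BioPAX reader preserves the entity/participant dichotomy", {
  d <- corpus_dir()
  g <- read_biopax(file.path(d, "pathwaycommons-biopax-synthetic.owl"))

  # each participant links to exactly one protein
  peps <- instances_of(g, "bp:physicalEntityParticipant")
  expect_gt(length(peps), 0L)
  for (p in peps) {
    expect_length(assertion_values(g, p, "bp:PHYSICAL-ENTITY"), 1L)
  }

  # interaction partner short names: RAD9-RAD53 and RAD9-CHK1, no MEC1
  partners <- lapply(instances_of(g, "bp:interaction"), function(x) {
    parts <- assertion_values(g, x, "bp:PARTICIPANTS")
    sort(vapply(parts, function(p) {
      e <- assertion_values(g, p, "bp:PHYSICAL-ENTITY")[[1]]
      assertion_values(g, e, "bp:SHORT-NAME")[[1]]
    }, character(1)))
  })
  expect_true(any(vapply(partners, function(p) setequal(p, c("RAD9", "RAD53")), logical(1))))
  expect_true(any(vapply(partners, function(p) setequal(p, c("RAD9", "CHK1")), logical(1))))
  expect_false(any(vapply(partners, function(p) "MEC1" %in% p, logical(1))))

  expect_true(all(vapply(names(g$instances), function(i) {
    identical(g$instances[[i]]$source, "PathwayCommons")
  }, logical(1))))

  # empty RDF graph -> empty instance set
  empty <- tempfile(fileext = ".owl")
  writeLines('<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"/>', empty)
  expect_length(read_biopax(empty)$instances, 0L)

  # unknown BioPAX class -> kept as generic entity with a warning
  odd <- tempfile(fileext = ".owl")
  writeLines('<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
    xmlns:bp="http://www.biopax.org/release/biopax-level2.owl#">
    <bp:weirdThing rdf:ID="w1"><bp:NAME>odd</bp:NAME></bp:weirdThing>
  </rdf:RDF>', odd)
  expect_warning(g3 <- read_biopax(odd), "unknown BioPAX class")
  expect_equal(instances_of(g3, "bp:entity"), "pathwaycommons#w1")

  expect_error(read_biopax(file.path(d, "uniprot-entries-synthetic.xml")),
               "expected rdf:RDF")
})

test_that("readers never merge records across sources", {
  g <- imported_graph()
  # RAD9 appears as (at least) three distinct instances before reconciliation
  rad9_ids <- names(g$instances)[vapply(names(g$instances), function(id) {
    "P14737" %in% assertion_values(g, id, "tuo:accession")
  }, logical(1))]
  expect_length(rad9_ids, 3L)
  expect_setequal(vapply(rad9_ids, function(i) g$instances[[i]]$source, character(1)),
                  c("UniProtKB", "BioGRID", "PathwayCommons"))
})
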
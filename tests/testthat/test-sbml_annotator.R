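toy_model_path <- function() file.path(corpus_dir(), "toy-model-synthetic.xml")

rad9_species_ids <- function(model) {
  vapply(Filter(function(s) {
    any(vapply(s$annotations, function(a) {
      grepl("uniprot:P14737$", a$uri)
    }, logical(1)))
  }, model$species), `[[`, character(1), "id")
}

test_that("the toy model parses with the expected checkpoint structure", {
  model <- read_sbml(toy_model_path())
  rad9_sp <- rad9_species_ids(model)
  expect_length(rad9_sp, 2L)  # active and inactive forms of one protein

  rad9_reactions <- Filter(function(r) {
    any(rad9_sp %in% rbmed:::reaction_species(r))
  }, model$reactions)
  expect_length(rad9_reactions, 4L)

  # the placeholder and known partners each share one reaction with RAD9
  partners <- setdiff(unlist(lapply(rad9_reactions, rbmed:::reaction_species)),
                      rad9_sp)
  expect_true(all(c("Rad9Kin", "ExoX", "Rad53", "Chk1") %in% partners))

  # modifiers are parsed as species references
  r1 <- model$reactions[[1]]
  expect_equal(r1$modifiers, "Rad9Kin")
})

test_that("SBML write/read round-trips byte-identically on the fixture", {
  path <- toy_model_path()
  model <- read_sbml(path)
  txt1 <- write_sbml(model)
  expect_identical(txt1, paste(readLines(path), collapse = "\n") |> paste0("\n"))
  tmp <- tempfile(fileext = ".xml")
  write_sbml(model, tmp)
  expect_identical(write_sbml(read_sbml(tmp)), txt1)
})

test_that("structural validation catches broken models", {
  model <- read_sbml(toy_model_path())
  expect_true(validate_sbml(model)$valid)

  bad <- model
  bad$reactions[[1]]$reactants <- c(bad$reactions[[1]]$reactants, "ghost_species")
  v <- validate_sbml(bad)
  expect_false(v$valid)
  expect_match(paste(v$errors, collapse = "; "), "ghost_species")

  bad2 <- model
  bad2$species[[1]]$sboTerm <- "SBO:12"
  expect_false(validate_sbml(bad2)$valid)

  bad3 <- model
  bad3$species[[2]]$id <- bad3$species[[1]]$id
  expect_false(validate_sbml(bad3)$valid)
})

test_that("species map to entities by accession, then name; ambiguity is an error", {
  res <- pipeline_result()
  model <- res$model_in
  graph <- res$graph
  mapping <- res$mapping

  # brute-force pairwise comparison oracle over (species, entity)
  entities <- instances_of(graph, "tuo:Protein")
  for (s in model$species) {
    by_acc <- character(); by_name <- character()
    for (e in entities) {
      eaccs <- assertion_values(graph, e, "tuo:accession")
      saccs <- unlist(lapply(s$annotations, function(a) {
        p <- parse_miriam_uri(a$uri)
        if (!is.null(p) && p$datatype == "uniprot") p$id
      }))
      if (length(intersect(eaccs, saccs))) by_acc <- c(by_acc, e)
      syns <- tolower(assertion_values(graph, e, "tuo:synonym"))
      if (!is.null(s$name) && tolower(s$name) %in% syns) by_name <- c(by_name, e)
    }
    want <- if (length(by_acc)) by_acc else by_name
    if (length(want) == 1L) {
      expect_equal(unname(mapping[[s$id]]), want, info = s$id)
    } else if (length(want) == 0L) {
      expect_false(s$id %in% names(mapping), info = s$id)
    }
  }
  # placeholders stay unmapped; both RAD9 forms map to one entity
  expect_false(any(c("Rad9Kin", "ExoX") %in% names(mapping)))
  expect_equal(unname(mapping[["Rad9_inactive"]]), unname(mapping[["Rad9_active"]]))

  # two distinct entities with the same synonym make the species ambiguous
  g2 <- clone_graph(graph)
  add_instance(g2, "dup#rad53", "tuo:Protein", "S")
  add_assertion(g2, "dup#rad53", "tuo:synonym", "Rad53")
  expect_error(map_species_to_entities(model, g2), "ambiguously matches")
})

test_that("annotation export is additive, idempotent, and URN-accurate", {
  res <- pipeline_result()
  graph <- res$graph
  registry <- load_miriam_registry(file.path(corpus_dir(), "miriam_registry.yaml"))
  export_map <- load_export_map(file.path(corpus_dir(), "export_map.yaml"))
  model <- res$model_in
  mapping <- res$mapping

  out <- suppressWarnings(
    export_annotations(model, graph, mapping, registry, export_map))

  for (sp in rad9_species_ids(model)) {
    anns <- Filter(function(a) a$species == sp, out$delta$annotations)
    expect_length(anns, 5L)
    sbo <- Filter(function(a) a$species == sp, out$delta$sbo)
    expect_length(sbo, 1L)
    expect_equal(sbo[[1]]$term, "SBO:0000252")
  }

  # every emitted URN parses back to a (database, id) pair on the entity
  for (a in out$delta$annotations) {
    p <- parse_miriam_uri(a$uri)
    expect_false(is.null(p))
    pairs <- rbmed:::entity_xref_pairs(graph, a$entity)
    hit <- any(vapply(pairs, function(x) {
      tok <- rbmed:::miriam_token(x$db, registry)
      !is.na(tok) && tok == p$datatype && x$id == p$id
    }, logical(1)))
    expect_true(hit, info = a$uri)
  }

  # nothing pre-existing was touched
  for (i in seq_along(model$species)) {
    old <- model$species[[i]]$annotations
    new <- out$model$species[[i]]$annotations
    expect_identical(new[seq_along(old)], old)
  }

  # second export adds nothing
  out2 <- suppressWarnings(
    export_annotations(out$model, graph, mapping, registry, export_map))
  expect_equal(sum(delta_counts(out2$delta)), 0L)
  expect_identical(write_sbml(out2$model), write_sbml(out$model))

  # unregistered databases are skipped with a warning, not emitted
  expect_warning(
    export_annotations(model, graph, mapping, registry, export_map),
    "EMBL.*not registered")
  all_uris <- vapply(out$delta$annotations, `[[`, character(1), "uri")
  expect_false(any(grepl("EMBL", all_uris, ignore.case = TRUE)))

  # a species mapped to an entity with no cross-references gets an empty delta
  g3 <- clone_graph(graph)
  add_instance(g3, "bare#p", "tuo:Protein", "S")
  add_assertion(g3, "bare#p", "tuo:synonym", "ExoX")
  map3 <- map_species_to_entities(model, g3, registry)
  out3 <- suppressWarnings(
    export_annotations(model, g3, map3, registry, export_map))
  expect_length(Filter(function(a) a$species == "ExoX", out3$delta$annotations), 0L)
})

test_that("skeleton proposals confirm known reactions and add only novel ones", {
  res <- pipeline_result()
  delta <- res$delta

  expect_length(delta$reactions_added, 2L)
  added_partners <- vapply(delta$reactions_added, function(r) {
    setdiff(r$reaction$reactants, rad9_species_ids(res$model_in))
  }, character(1))
  expect_setequal(added_partners, c("Mec1", "Rad17"))
  for (r in delta$reactions_added) {
    expect_length(r$reaction$products, 0L)   # reactants only: no kinetics
    expect_length(r$reaction$modifiers, 0L)
  }

  confirmed_cls <- vapply(delta$confirmed, `[[`, character(1), "class")
  expect_setequal(confirmed_cls,
                  c("tuo:Rad9Rad53Interaction", "tuo:Rad9Chk1Interaction"))
  # confirmed interactions were not re-added
  added_cls <- vapply(delta$reactions_added, `[[`, character(1), "class")
  expect_length(intersect(confirmed_cls, added_cls), 0L)

  # the kinase placeholder is provisionally identified, never substituted
  expect_length(delta$candidates, 1L)
  cand <- delta$candidates[[1]]
  expect_equal(cand$placeholder, "Rad9Kin")
  expect_true("P38111" %in% assertion_values(res$graph, cand$entity, "tuo:accession"))
  expect_true("Rad9Kin" %in% rbmed:::species_ids(res$model))  # placeholder still there

  # a partner absent from the model is added as an annotated species
  model_small <- res$model_in
  keep <- !rbmed:::species_ids(model_small) %in% c("Mec1", "Rad17")
  model_small$species <- model_small$species[keep]
  model_small$reactions <- Filter(function(r) {
    all(!c("Mec1", "Rad17") %in% rbmed:::reaction_species(r))
  }, model_small$reactions)
  mapping_small <- map_species_to_entities(model_small, res$graph)
  prop <- propose_new_reactions(
    model_small, res$graph, mapping_small,
    unlist(res$config$interaction_classes))
  expect_length(prop$delta$species_added, 2L)
  new_sp <- prop$delta$species_added[[1]]$species
  expect_gt(length(new_sp$annotations), 0L)
  expect_true(validate_sbml(prop$model)$valid)
})

test_that("the recorded delta replays the input model into the output model", {
  res <- pipeline_result()
  replayed <- apply_delta(res$model_in, res$delta)
  expect_identical(write_sbml(replayed), write_sbml(res$model))
  # and the annotated output is structurally valid SBML
  expect_true(validate_sbml(res$model)$valid)
})
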
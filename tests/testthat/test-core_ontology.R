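test_that("the core schema is source-format independent and loads cleanly", {
  schema <- load_core_schema(file.path(corpus_dir(), "core_schema.yaml"))
  g <- schema$graph
  expect_true(all(c("tuo:Protein", "tuo:Rad9", "tuo:Process",
                    "tuo:ParticipantRole", "tuo:CrossReference") %in%
                    names(g$classes)))
  # decoupling: no class or property name mentions a source format
  all_names <- c(names(g$classes), names(g$properties))
  expect_false(any(grepl("up:|psi:|bp:|uniprot|biogrid|biopax|psimif",
                         all_names, ignore.case = TRUE)))
  expect_length(schema$defined, 4L)
  expect_true(all(names(schema$defined) %in% names(g$classes)))
})

test_that("equivalence reconciliation groups the three RAD9 records into one set", {
  g <- imported_graph()
  partition <- assert_equivalences(g)
  rad9_set <- Filter(function(s) any(vapply(s, function(id) {
    "P14737" %in% assertion_values(g, id, "tuo:accession")
  }, logical(1))), partition$sets)
  expect_length(rad9_set, 1L)
  expect_length(rad9_set[[1]], 3L)
  expect_setequal(vapply(rad9_set[[1]], function(i) g$instances[[i]]$source,
                         character(1)),
                  c("UniProtKB", "BioGRID", "PathwayCommons"))
  # every instance id appears in exactly one set
  all_ids <- unlist(partition$sets)
  expect_setequal(all_ids, names(g$instances))
  expect_equal(anyDuplicated(all_ids), 0L)
})

test_that("the partition equals a connected-components oracle on random key sets", {
  for (seed in 1:4) {
    set.seed(seed)
    g <- instance_graph()
    add_class(g, "tuo:Protein")
    add_property(g, "tuo:accession", "data")
    add_property(g, "tuo:primaryName", "data")
    add_property(g, "tuo:taxonId", "data")
    n <- 15L
    ids <- sprintf("s%d#p", seq_len(n))
    accs <- sprintf("ACC%d", seq_len(6L))
    keys_by_id <- list()
    for (i in seq_len(n)) {
      add_instance(g, ids[[i]], "tuo:Protein", "S")
      mine <- sample(accs, sample.int(2L, 1L))
      for (a in mine) add_assertion(g, ids[[i]], "tuo:accession", a)
      keys_by_id[[ids[[i]]]] <- mine
    }
    got <- assert_equivalences(g, keys = "accession")$sets
    want <- oracle_partition(ids, keys_by_id)
    norm <- norm_sets
    expect_equal(norm(got), norm(want), info = sprintf("seed %d", seed))
  }
})

test_that("a shared key across conflicting taxa warns and does not merge", {
  g <- instance_graph()
  add_class(g, "tuo:Protein")
  add_property(g, "tuo:accession", "data")
  add_property(g, "tuo:taxonId", "data")
  add_instance(g, "a#1", "tuo:Protein", "S1")
  add_instance(g, "b#1", "tuo:Protein", "S2")
  add_assertion(g, "a#1", "tuo:accession", "P1")
  add_assertion(g, "b#1", "tuo:accession", "P1")
  add_assertion(g, "a#1", "tuo:taxonId", "4932")
  add_assertion(g, "b#1", "tuo:taxonId", "9606")
  expect_warning(p <- assert_equivalences(g, keys = "accession"),
                 "different taxon ids")
  expect_length(p$sets, 2L)
})

test_that("merging canonicalizes without information loss", {
  g <- imported_graph()
  partition <- assert_equivalences(g)

  # distinct (property, value) pairs are conserved by merging (dedup only)
  pair_set <- function(gr, remap = identity) {
    out <- character()
    for (inst in gr$instances) {
      for (a in inst$assertions) {
        v <- if (!is.null(a$value$ref)) paste0("R:", remap(a$value$ref))
             else paste0("L:", a$value$value)
        out <- c(out, paste(a$property, v))
      }
    }
    unique(out)
  }
  canon_of <- function(p) {
    m <- character()
    for (s in p$sets) for (id in s) m[[id]] <- s[[1]]
    m
  }
  cmap <- canon_of(partition)
  before <- pair_set(g, remap = function(id) cmap[[id]])
  merge_equivalents(g, partition)
  after <- pair_set(g)
  expect_setequal(after, before)

  # the merged RAD9 carries cross-references from all contributing sources
  rad9 <- names(g$instances)[vapply(names(g$instances), function(id) {
    "P14737" %in% assertion_values(g, id, "tuo:accession")
  }, logical(1))]
  expect_length(rad9, 1L)
  xref_dbs <- unlist(lapply(assertion_values(g, rad9, "tuo:hasCrossReference"),
                            function(x) assertion_values(g, x, "tuo:databaseName")))
  expect_true(all(c("IntAct", "SGD", "Pathway Commons") %in% xref_dbs))
  expect_setequal(g$instances[[rad9]]$source,
                  c("UniProtKB", "BioGRID", "PathwayCommons"))

  # singleton sets leave instances unchanged
  g2 <- instance_graph()
  add_class(g2, "C")
  add_instance(g2, "x#1", "C", "S")
  p2 <- assert_equivalences(g2)
  merge_equivalents(g2, p2)
  expect_equal(names(g2$instances), "x#1")
})

test_that("reconciliation is deterministic under shuffled insertion order", {
  build <- function(order) {
    g <- instance_graph()
    add_class(g, "tuo:Protein")
    add_property(g, "tuo:accession", "data")
    for (id in order) add_instance(g, id, "tuo:Protein", "S")
    for (id in order) add_assertion(g, id, "tuo:accession",
                                    if (id %in% c("a#1", "b#1")) "P1" else "P2")
    g
  }
  norm <- function(p) norm_sets(p$sets)
  p1 <- assert_equivalences(build(c("a#1", "b#1", "c#1", "d#1")))
  p2 <- assert_equivalences(build(c("d#1", "c#1", "b#1", "a#1")))
  expect_equal(norm(p1), norm(p2))
})

test_that("organism restriction removes mismatching proteins and dangling structure", {
  g <- imported_graph()
  merge_equivalents(g, assert_equivalences(g))

  human <- names(g$instances)[vapply(names(g$instances), function(id) {
    "9606" %in% assertion_values(g, id, "tuo:taxonId")
  }, logical(1))]
  expect_length(human, 1L)

  # independent scan of what should go: mismatching proteins + dependents
  res <- restrict_organism(g, 4932)
  expect_true(human %in% res$removed)
  expect_false(human %in% names(g$instances))
  # all yeast proteins retained
  expect_true(all(vapply(instances_of(g, "tuo:Protein"), function(id) {
    tx <- assertion_values(g, id, "tuo:taxonId")
    !length(tx) || "4932" %in% tx
  }, logical(1))))
  expect_true(validate_graph(g))

  # a graph where everything matches is untouched
  g2 <- clone_graph(g)
  res2 <- restrict_organism(g2, 4932)
  expect_length(res2$removed, 0L)
  expect_identical(write_turtle(g2), write_turtle(g))

  # dangling roles and processes cascade away with their protein
  g3 <- instance_graph()
  add_class(g3, "tuo:Protein"); add_class(g3, "tuo:ParticipantRole")
  add_class(g3, "tuo:Process")
  add_property(g3, "tuo:taxonId", "data")
  add_property(g3, "tuo:playedBy", "object")
  add_property(g3, "tuo:plays", "object")
  add_property(g3, "tuo:hasParticipant", "object")
  add_instance(g3, "x#p", "tuo:Protein", "S")
  add_assertion(g3, "x#p", "tuo:taxonId", "9606")
  add_instance(g3, "x#q", "tuo:Protein", "S")
  add_assertion(g3, "x#q", "tuo:taxonId", "4932")
  add_instance(g3, "x#role", "tuo:ParticipantRole", "S")
  add_instance(g3, "x#role2", "tuo:ParticipantRole", "S")
  add_instance(g3, "x#proc", "tuo:Process", "S")
  add_assertion(g3, "x#role", "tuo:playedBy", "x#p")
  add_assertion(g3, "x#role2", "tuo:playedBy", "x#q")
  add_assertion(g3, "x#proc", "tuo:hasParticipant", "x#role")
  add_assertion(g3, "x#proc", "tuo:hasParticipant", "x#role2")
  add_assertion(g3, "x#q", "tuo:plays", "x#role2")
  res3 <- restrict_organism(g3, 4932)
  expect_setequal(res3$removed, c("x#p", "x#role", "x#proc"))
  expect_true(validate_graph(g3))

  # proteins with no taxon id at all are retained with a warning
  g4 <- instance_graph()
  add_class(g4, "tuo:Protein")
  add_property(g4, "tuo:taxonId", "data")
  add_instance(g4, "x#untagged", "tuo:Protein", "S")
  expect_warning(res4 <- restrict_organism(g4, 4932), "no taxon id")
  expect_equal(res4$kept_without_taxon, "x#untagged")
  expect_true("x#untagged" %in% names(g4$instances))
})
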
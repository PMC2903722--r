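# Shared fixtures: the synthetic corpus and the full pipeline run are
# generated once per test session and cached, since they are deterministic.

.rbmed_cache <- new.env(parent = emptyenv())

corpus_dir <- function() {
  if (is.null(.rbmed_cache$corpus)) {
    dir <- file.path(tempdir(), "rbmed-test-corpus")
    generate_corpus(dir)
    .rbmed_cache$corpus <- dir
  }
  .rbmed_cache$corpus
}

pipeline_result <- function() {
  if (is.null(.rbmed_cache$pipeline)) {
    # the corpus deliberately carries an unregistered EMBL cross-reference,
    # whose skip-warning is under test elsewhere
    .rbmed_cache$pipeline <- suppressWarnings(
      run_pipeline(file.path(corpus_dir(), "pipeline.yaml")))
  }
  .rbmed_cache$pipeline
}

# graph state after import rules but before reconciliation/restriction
imported_graph <- function() {
  if (is.null(.rbmed_cache$imported)) {
    d <- corpus_dir()
    gs <- list(
      read_uniprot(file.path(d, "uniprot-entries-synthetic.xml")),
      read_psimif(file.path(d, "biogrid-psimif-synthetic.xml")),
      read_biopax(file.path(d, "pathwaycommons-biopax-synthetic.owl"))
    )
    schema <- load_core_schema(file.path(d, "core_schema.yaml"))
    g <- graph_union(c(gs, list(schema$graph)))
    rules <- unlist(lapply(file.path(d, c("import_uniprot.rules",
                                          "import_psimif.rules",
                                          "import_biopax.rules")),
                           parse_rules_file), recursive = FALSE)
    apply_rules(g, rules)
    .rbmed_cache$imported <- g
  }
  clone_graph(.rbmed_cache$imported)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
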
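# Export of integrated knowledge onto an SBML model: species-to-entity
# mapping, MIRIAM/SBO/name annotation export, and skeleton-reaction
# proposals for interactions absent from the curated model.  Every change is
# recorded in a ModelDelta that is traceable to core-graph instances (and
# their source provenance) and that, applied to the input model, reproduces
# the output model exactly.  Nothing is ever modified or removed: export is
# strictly additive and idempotent.

#' Load the export configuration
#'
#' YAML with: `qualifier` (biology qualifier used for identity
#' cross-references, default `is`), `uri_style` (`urn` or `url`), and
#' `sbo_terms` (map core class -> SBO term assigned to species mapped to
#' entities of that class, when the species has none).
#'
#' @param path Export map file; defaults to the one shipped with the package.
#' @return A list.
#' @export
load_export_map <- function(path = system.file("extdata", "export_map.yaml",
                                               package = "rbmed")) {
  spec <- yaml::read_yaml(path)
  spec$qualifier <- spec$qualifier %||% "is"
  spec$uri_style <- spec$uri_style %||% "urn"
  if (!spec$qualifier %in% MIRIAM_QUALIFIERS) {
    stop(sprintf("export map: unknown qualifier '%s'", spec$qualifier))
  }
  spec
}

new_delta <- function() {
  structure(list(annotations = list(), sbo = list(), names = list(),
                 species_added = list(), reactions_added = list(),
                 confirmed = list(), candidates = list()),
            class = "ModelDelta")
}

#' Summarize a ModelDelta
#' @param delta A `ModelDelta`.
#' @return Named integer vector of per-category counts.
#' @export
delta_counts <- function(delta) {
  vapply(list(
    annotations_added = delta$annotations, sbo_terms_added = delta$sbo,
    names_added = delta$names, species_added = delta$species_added,
    reactions_added = delta$reactions_added,
    interactions_confirmed = delta$confirmed,
    placeholder_candidates = delta$candidates
  ), length, integer(1))
}

#' @export
print.ModelDelta <- function(x, ...) {
  counts <- delta_counts(x)
  cat("<ModelDelta>\n")
  for (nm in names(counts)) cat(sprintf("  %-24s %d\n", nm, counts[[nm]]))
  invisible(x)
}

merge_deltas <- function(a, b) {
  for (nm in names(unclass(b))) a[[nm]] <- c(a[[nm]], b[[nm]])
  a
}

entity_classes_with_closure <- function(graph, id) {
  inst <- graph$instances[[id]]
  unique(unlist(lapply(inst$classes, function(cls) class_ancestors(graph, cls))))
}

# all (db, id) cross-reference pairs of an entity: its accessions (UniProtKB)
# plus its CrossReference instances
entity_xref_pairs <- function(graph, entity) {
  pairs <- list()
  for (acc in assertion_values(graph, entity, "tuo:accession")) {
    pairs[[length(pairs) + 1L]] <- list(db = "UniProtKB", id = acc)
  }
  for (xr in assertion_values(graph, entity, "tuo:hasCrossReference")) {
    dbs <- assertion_values(graph, xr, "tuo:databaseName")
    ids <- assertion_values(graph, xr, "tuo:databaseId")
    if (length(dbs) && length(ids)) {
      pairs[[length(pairs) + 1L]] <- list(db = dbs[[1]], id = ids[[1]])
    }
  }
  pairs
}

#' Map model species to canonical core entities
#'
#' A species maps to an entity when (a) one of its existing MIRIAM UniProtKB
#' annotations matches the entity's accession, or failing that (b) its name
#' equals an entity synonym case-insensitively.  Many species may map to one
#' entity (e.g. active and inactive forms of one protein); a species
#' matching two distinct canonical entities is an error listing the
#' candidates, never a silent choice.  Placeholder species with neither
#' match stay unmapped.
#'
#' @param model An `sbml_model`.
#' @param graph Reconciled core `InstanceGraph`.
#' @param registry MIRIAM registry (used to recognize UniProtKB URNs).
#' @param protein_class Core class whose instances are mapping candidates.
#' @return Named character vector: species id -> entity id (mapped species
#'   only).
#' @export
map_species_to_entities <- function(model, graph,
                                    registry = load_miriam_registry(),
                                    protein_class = "tuo:Protein") {
  entities <- instances_of(graph, protein_class)
  acc_index <- lapply(entities, function(e) assertion_values(graph, e, "tuo:accession"))
  syn_index <- lapply(entities, function(e) {
    tolower(assertion_values(graph, e, "tuo:synonym"))
  })
  names(acc_index) <- names(syn_index) <- entities
  out <- character()
  for (s in model$species) {
    hits <- character()
    uris <- vapply(s$annotations, `[[`, character(1), "uri")
    accs <- character()
    for (u in uris) {
      p <- parse_miriam_uri(u)
      if (!is.null(p) && p$datatype == "uniprot") accs <- c(accs, p$id)
    }
    if (length(accs)) {
      hits <- entities[vapply(entities, function(e) any(accs %in% acc_index[[e]]),
                              logical(1))]
    }
    if (!length(hits) && !is_blank(s$name)) {
      hits <- entities[vapply(entities, function(e) tolower(s$name) %in% syn_index[[e]],
                              logical(1))]
    }
    hits <- unique(hits)
    if (length(hits) > 1L) {
      stop(sprintf("species '%s' ambiguously matches %d entities: %s",
                   s$id, length(hits), paste(hits, collapse = ", ")))
    }
    if (length(hits) == 1L) out[[s$id]] <- hits
  }
  out
}

# MIRIAM annotations an entity contributes, with provenance; unregistered
# database names are skipped with a warning (no malformed URN is emitted)
entity_annotations <- function(graph, entity, registry, qualifier, style) {
  anns <- list()
  seen <- character()
  for (p in entity_xref_pairs(graph, entity)) {
    uri <- miriam_uri(p$db, p$id, registry, style)
    if (is.na(uri)) {
      warning(sprintf("entity '%s': cross-reference database '%s' is not registered; skipped",
                      entity, p$db))
      next
    }
    if (uri %in% seen) next
    seen <- c(seen, uri)
    anns[[length(anns) + 1L]] <- list(qualifier = qualifier, uri = uri)
  }
  anns
}

#' Export annotations from the core graph onto a model
#'
#' For every mapped species: one MIRIAM annotation per distinct
#' cross-reference of its entity (deduplicated against annotations already
#' on the species), an SBO term when the entity's class dictates one and the
#' species has none, and a display name when the species has none.  Nothing
#' is modified or removed, so running the export twice yields an empty
#' second delta.
#'
#' @param model An `sbml_model`.
#' @param graph Reconciled core `InstanceGraph`.
#' @param mapping From [map_species_to_entities()].
#' @param registry MIRIAM registry.
#' @param export_map From [load_export_map()].
#' @return `list(model = <annotated model>, delta = <ModelDelta>)`.
#' @export
export_annotations <- function(model, graph, mapping,
                               registry = load_miriam_registry(),
                               export_map = load_export_map()) {
  delta <- new_delta()
  qualifier <- export_map$qualifier
  style <- export_map$uri_style
  for (i in seq_along(model$species)) {
    s <- model$species[[i]]
    if (!s$id %in% names(mapping)) next
    entity <- mapping[[s$id]]
    sources <- graph$instances[[entity]]$source
    existing <- vapply(s$annotations, `[[`, character(1), "uri")
    for (a in entity_annotations(graph, entity, registry, qualifier, style)) {
      if (a$uri %in% existing) next
      s$annotations[[length(s$annotations) + 1L]] <- a
      existing <- c(existing, a$uri)
      delta$annotations[[length(delta$annotations) + 1L]] <-
        list(species = s$id, qualifier = a$qualifier, uri = a$uri,
             entity = entity, sources = sources)
    }
    if (is_blank(s$sboTerm)) {
      ecls <- entity_classes_with_closure(graph, entity)
      for (cls in names(export_map$sbo_terms %||% list())) {
        if (cls %in% ecls) {
          s$sboTerm <- export_map$sbo_terms[[cls]]
          delta$sbo[[length(delta$sbo) + 1L]] <-
            list(species = s$id, term = s$sboTerm, entity = entity,
                 sources = sources)
          break
        }
      }
    }
    if (is_blank(s$name)) {
      nm <- assertion_values(graph, entity, "tuo:primaryName")
      if (length(nm)) {
        s$name <- nm[[1]]
        delta$names[[length(delta$names) + 1L]] <-
          list(species = s$id, name = s$name, entity = entity, sources = sources)
      }
    }
    model$species[[i]] <- s
  }
  list(model = model, delta = delta)
}

sanitize_sid <- function(x) {
  x <- gsub("[^A-Za-z0-9_]+", "_", x)
  if (!grepl("^[A-Za-z_]", x)) x <- paste0("s_", x)
  x
}

# entity pairs asserted by classified interaction instances, with provenance
classified_interaction_pairs <- function(graph, classified) {
  pairs <- list()
  index <- character()
  for (dc in classified) {
    for (pid in instances_of(graph, dc)) {
      roles <- assertion_values(graph, pid, "tuo:hasParticipant")
      ents <- unique(unlist(lapply(roles, function(r) {
        assertion_values(graph, r, "tuo:playedBy")
      })))
      if (length(ents) != 2L) next
      key <- paste(sort(ents), collapse = "|")
      src <- graph$instances[[pid]]$source
      if (key %in% index) {
        j <- match(key, index)
        pairs[[j]]$sources <- unique(c(pairs[[j]]$sources, src))
        pairs[[j]]$interactions <- c(pairs[[j]]$interactions, pid)
      } else {
        index <- c(index, key)
        pairs[[length(pairs) + 1L]] <- list(
          entities = ents, class = dc, sources = src, interactions = pid)
      }
    }
  }
  pairs
}

#' Propose skeleton reactions for classified interactions
#'
#' Each classified interaction between two entities is compared with the
#' model: if some existing reaction already involves species mapped to both
#' entities, the interaction is *confirmed* (recorded, never re-added);
#' otherwise a skeleton reaction is added, reactants only, with no kinetic
#' law or parameters, as a placeholder for manual curation.  A partner
#' entity with no species in the model is added as a new species carrying
#' the entity's MIRIAM annotations.  Finally, unmapped placeholder species
#' that act on a mapped species (reactant or modifier in one of its
#' reactions) are screened against the newly proposed partners: a partner
#' whose function annotation describes it as a kinase of the placeholder's
#' co-reactant, when the placeholder's own label hints at a kinase, is
#' reported as a *candidate* identity — reported in the delta only, never
#' substituted into the model.
#'
#' @param model An `sbml_model` (typically the output of
#'   [export_annotations()]).
#' @param graph Reconciled core `InstanceGraph` after defined-class
#'   classification.
#' @param mapping From [map_species_to_entities()].
#' @param classified Character vector of defined interaction class names.
#' @param registry,export_map Used to annotate newly added species.
#' @return `list(model =, delta =)`.
#' @export
propose_new_reactions <- function(model, graph, mapping, classified,
                                  registry = load_miriam_registry(),
                                  export_map = load_export_map()) {
  delta <- new_delta()
  species_of_entity <- function(e, map) names(map)[map == e]
  pairs <- classified_interaction_pairs(graph, classified)
  mapping_now <- mapping
  for (p in pairs) {
    a <- p$entities[[1]]; b <- p$entities[[2]]
    sp_a <- species_of_entity(a, mapping_now)
    sp_b <- species_of_entity(b, mapping_now)
    existing <- NULL
    for (r in model$reactions) {
      involved <- reaction_species(r)
      if (any(sp_a %in% involved) && any(sp_b %in% involved)) {
        existing <- r$id %||% "<anonymous>"
        break
      }
    }
    if (!is.null(existing)) {
      delta$confirmed[[length(delta$confirmed) + 1L]] <- list(
        entities = c(a, b), reaction = existing, class = p$class,
        sources = p$sources, interactions = p$interactions)
      next
    }
    # add missing partner species from the core entity
    for (e in c(a, b)) {
      if (length(species_of_entity(e, mapping_now))) next
      nm <- assertion_values(graph, e, "tuo:primaryName")
      nm <- if (length(nm)) nm[[1]] else sub("^.*#", "", e)
      sid <- sanitize_sid(nm)
      while (sid %in% species_ids(model)) sid <- paste0(sid, "_new")
      sp <- list(id = sid, metaid = paste0("meta_", sid), name = nm,
                 compartment = model$compartments[[1]]$id,
                 initialAmount = "0", sboTerm = NULL,
                 annotations = entity_annotations(graph, e, registry,
                                                  export_map$qualifier %||% "is",
                                                  export_map$uri_style %||% "urn"))
      model$species[[length(model$species) + 1L]] <- sp
      mapping_now[[sid]] <- e
      delta$species_added[[length(delta$species_added) + 1L]] <-
        list(species = sp, entity = e, sources = graph$instances[[e]]$source)
    }
    ra <- species_of_entity(a, mapping_now)[[1]]
    rb <- species_of_entity(b, mapping_now)[[1]]
    rid <- sanitize_sid(paste0("proposed_", ra, "_", rb))
    while (rid %in% reaction_ids(model)) rid <- paste0(rid, "_new")
    reaction <- list(id = rid, metaid = NULL,
                     name = sprintf("Proposed interaction: %s - %s",
                                    get_species(model, ra)$name %||% ra,
                                    get_species(model, rb)$name %||% rb),
                     reversible = FALSE,
                     reactants = c(ra, rb), products = character(),
                     modifiers = character(), annotations = list())
    model$reactions[[length(model$reactions) + 1L]] <- reaction
    delta$reactions_added[[length(delta$reactions_added) + 1L]] <- list(
      reaction = reaction, entities = c(a, b), class = p$class,
      sources = p$sources, interactions = p$interactions)
  }
  # provisional identification of placeholder species
  new_partner_entities <- unique(unlist(lapply(delta$reactions_added,
                                               `[[`, "entities")))
  placeholders <- list()
  for (r in model$reactions) {
    acting <- unique(c(r$reactants, r$modifiers))
    mapped_here <- intersect(reaction_species(r), names(mapping))
    if (!length(mapped_here)) next
    for (sp in setdiff(acting, names(mapping))) {
      co <- unique(unname(mapping[mapped_here]))
      placeholders[[sp]] <- unique(c(placeholders[[sp]] %||% character(), co))
    }
  }
  for (sp in names(placeholders)) {
    sp_rec <- get_species(model, sp)
    label <- sp_rec$name %||% sp
    if (!grepl("kin", label, ignore.case = TRUE)) next
    co_entities <- placeholders[[sp]]
    for (e in new_partner_entities) {
      if (e %in% co_entities) next
      notes <- assertion_values(graph, e, "tuo:functionNote")
      if (!length(notes) || !any(grepl("kinase", notes, ignore.case = TRUE))) next
      for (co in co_entities) {
        syns <- assertion_values(graph, co, "tuo:synonym")
        hit <- any(vapply(syns, function(sy) {
          any(grepl(tolower(sy), tolower(notes), fixed = TRUE))
        }, logical(1)))
        if (hit) {
          pretty <- function(ent) {
            nm <- assertion_values(graph, ent, "tuo:primaryName")
            if (length(nm)) nm[[1]] else sub("^.*#", "", ent)
          }
          delta$candidates[[length(delta$candidates) + 1L]] <- list(
            placeholder = sp, entity = e,
            sources = graph$instances[[e]]$source,
            reason = sprintf(
              "'%s' acts on %s; %s is annotated as a kinase of that protein",
              label, pretty(co), pretty(e)))
          break
        }
      }
    }
  }
  list(model = model, delta = delta)
}

#' Apply a recorded ModelDelta to a model
#'
#' Replays a delta (annotations, SBO terms, names, added species, added
#' reactions) on a model.  Applying the delta recorded by a pipeline run to
#' the run's input model reproduces its output model exactly, which makes
#' every model change auditable.
#'
#' @param model An `sbml_model`.
#' @param delta A `ModelDelta`.
#' @return The modified model.
#' @export
apply_delta <- function(model, delta) {
  idx <- function(id) match(id, species_ids(model))
  for (a in delta$annotations) {
    i <- idx(a$species)
    model$species[[i]]$annotations[[length(model$species[[i]]$annotations) + 1L]] <-
      list(qualifier = a$qualifier, uri = a$uri)
  }
  for (a in delta$sbo) model$species[[idx(a$species)]]$sboTerm <- a$term
  for (a in delta$names) model$species[[idx(a$species)]]$name <- a$name
  for (a in delta$species_added) {
    model$species[[length(model$species) + 1L]] <- a$species
  }
  for (a in delta$reactions_added) {
    model$reactions[[length(model$reactions) + 1L]] <- a$reaction
  }
  model
}

#' Serialize a ModelDelta to JSON
#'
#' @param delta A `ModelDelta`.
#' @param path Output path; when `NULL` the JSON text is returned.
#' @return JSON text (invisibly when written).
#' @export
write_delta <- function(delta, path = NULL) {
  payload <- list(counts = as.list(delta_counts(delta)),
                  changes = unclass(delta))
  txt <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
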
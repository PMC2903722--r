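# The compact core ("telomere") domain ontology: schema loading from a
# declarative file, key-based equivalence reconciliation (the automated
# counterpart of pairwise sameAs declarations), merging of equivalent
# instances, and restriction to the organism of interest.  The core schema
# never references any source format name: it models proteins, the roles
# they play in processes, organisms and cross-references.

#' Load the core ontology schema
#'
#' The schema file is YAML with three maps: `classes` (class -> parent or
#' `~`), `properties` (name -> `{kind: object|data}`) and `defined_classes`
#' (class -> Manchester-style class expression text).  Defined classes are
#' declared as ordinary classes in the schema graph; their expressions are
#' returned separately for [classify_instances()].
#'
#' @param path Schema file path; defaults to the schema shipped with the
#'   package.
#' @return `list(graph = <schema InstanceGraph>, defined = <named list of
#'   expression text>)`.
#' @export
load_core_schema <- function(path = system.file("schema", "core_schema.yaml",
                                                package = "rbmed")) {
  spec <- yaml::read_yaml(path)
  g <- instance_graph()
  remaining <- names(spec$classes)
  while (length(remaining)) {
    progressed <- FALSE
    for (nm in remaining) {
      parent <- spec$classes[[nm]]
      parents <- if (is.null(parent)) character() else as.character(parent)
      if (all(parents %in% names(g$classes))) {
        add_class(g, nm, parents)
        remaining <- setdiff(remaining, nm)
        progressed <- TRUE
      }
    }
    if (!progressed) {
      stop(sprintf("core schema: unresolvable parent(s) for: %s",
                   paste(remaining, collapse = ", ")))
    }
  }
  for (nm in names(spec$properties)) {
    add_property(g, nm, spec$properties[[nm]]$kind)
  }
  defined <- spec$defined_classes %||% list()
  for (nm in names(defined)) {
    if (is.null(g$classes[[nm]])) {
      stop(sprintf("core schema: defined class '%s' missing from classes map", nm))
    }
  }
  list(graph = g, defined = defined)
}

# ---------------------------------------------------------------------------
# reconciliation

core_key_extractors <- list(
  # shared UniProtKB accession (the primary reconciliation key)
  accession = function(graph, id) {
    vals <- assertion_values(graph, id, "tuo:accession")
    if (length(vals)) paste0("acc:", vals) else character()
  },
  # fallback: exact case-insensitive primary name + same taxon
  name_taxon = function(graph, id) {
    nm <- assertion_values(graph, id, "tuo:primaryName")
    tx <- assertion_values(graph, id, "tuo:taxonId")
    if (length(nm) && length(tx)) {
      paste0("nm:", tolower(nm[[1]]), "|", tx[[1]])
    } else {
      character()
    }
  }
)

uf_new <- function(ids) {
  e <- new.env(parent = emptyenv())
  e$parent <- stats::setNames(ids, ids)
  e
}
uf_find <- function(e, x) {
  while (e$parent[[x]] != x) {
    e$parent[[x]] <- e$parent[[e$parent[[x]]]]
    x <- e$parent[[x]]
  }
  x
}
uf_union <- function(e, a, b) {
  ra <- uf_find(e, a); rb <- uf_find(e, b)
  if (ra != rb) e$parent[[rb]] <- ra
  invisible(e)
}

#' Compute the equivalence partition of core instances
#'
#' Instances sharing any key value are declared equivalent; the partition is
#' the reflexive-symmetric-transitive closure of those pairwise
#' declarations.  Two instances that share a key but carry conflicting taxon
#' ids are *not* merged (a conflict warning is raised instead), so an
#' accession collision across organisms never collapses distinct proteins.
#'
#' @param graph An `InstanceGraph` (after import rules).
#' @param keys Character vector naming key extractors, in priority order.
#'   Built-ins: `"accession"` (shared `tuo:accession` value) and
#'   `"name_taxon"` (case-insensitive `tuo:primaryName` + equal
#'   `tuo:taxonId`).
#' @param within Optional class identifier restricting which instances are
#'   candidates (others stay singletons).  Default considers every instance.
#' @return An `EquivalencePartition`: `list(sets = <list of id vectors>)`,
#'   sets ordered by first member's insertion order; every instance id of
#'   the graph appears in exactly one set.
#' @export
assert_equivalences <- function(graph, keys = c("accession", "name_taxon"),
                                within = NULL) {
  extractors <- lapply(keys, function(k) {
    fn <- core_key_extractors[[k]]
    if (is.null(fn)) stop(sprintf("unknown reconciliation key '%s'", k))
    fn
  })
  all_ids <- names(graph$instances)
  candidates <- if (is.null(within)) all_ids else instances_of(graph, within)
  uf <- uf_new(all_ids)
  key_groups <- list()
  for (id in candidates) {
    for (fn in extractors) {
      for (k in fn(graph, id)) {
        key_groups[[k]] <- c(key_groups[[k]], id)
      }
    }
  }
  for (k in names(key_groups)) {
    grp <- unique(key_groups[[k]])
    if (length(grp) < 2L) next
    taxa <- vapply(grp, function(id) {
      tx <- assertion_values(graph, id, "tuo:taxonId")
      if (length(tx)) tx[[1]] else NA_character_
    }, character(1))
    known <- unique(taxa[!is.na(taxa)])
    if (length(known) > 1L) {
      warning(sprintf(
        "reconciliation conflict on key '%s': instances carry different taxon ids (%s); not merged across taxa",
        k, paste(known, collapse = ", ")))
    }
    # merge within each taxon subgroup; taxon-less instances join the group
    # only when the taxon is unambiguous
    groups <- if (length(known) <= 1L) {
      list(grp)
    } else {
      lapply(known, function(t) grp[!is.na(taxa) & taxa == t])
    }
    for (sub in groups) {
      if (length(sub) > 1L) {
        for (i in 2:length(sub)) uf_union(uf, sub[[1]], sub[[i]])
      }
    }
  }
  roots <- vapply(all_ids, function(id) uf_find(uf, id), character(1))
  sets <- split(all_ids, factor(roots, levels = unique(roots)))
  names(sets) <- NULL
  structure(list(sets = sets), class = "EquivalencePartition")
}

#' Merge equivalent instances into one canonical instance per set
#'
#' The canonical instance of each set is its earliest member (graph
#' insertion order).  It receives the union of the set's class memberships,
#' assertions and provenance labels; every object reference in the graph
#' that pointed at a merged member is rewritten to the canonical id.
#' Assertion multisets are preserved up to deduplication, so every pre-merge
#' assertion is recoverable from some canonical instance.
#'
#' @param graph An `InstanceGraph`, mutated in place.
#' @param partition An `EquivalencePartition` from [assert_equivalences()].
#' @return The graph, invisibly; the canonical-id map is attached as
#'   attribute `"canonical"` (named character vector member -> canonical).
#' @export
merge_equivalents <- function(graph, partition) {
  stopifnot(inherits(partition, "EquivalencePartition"))
  canon <- character()
  for (set in partition$sets) {
    members <- names(graph$instances)[names(graph$instances) %in% set]
    if (!length(members)) next
    canon[members] <- members[[1]]
  }
  remap <- function(id) if (id %in% names(canon)) canon[[id]] else id
  new_instances <- list()
  for (id in names(graph$instances)) {
    target <- remap(id)
    inst <- graph$instances[[id]]
    if (is.null(new_instances[[target]])) {
      new_instances[[target]] <- list(id = target, classes = character(),
                                      source = character(),
                                      assertions = list(), akeys = character())
    }
    tgt <- new_instances[[target]]
    tgt$classes <- unique(c(tgt$classes, inst$classes))
    tgt$source <- unique(c(tgt$source, inst$source))
    for (a in inst$assertions) {
      v <- a$value
      if (is_ref(v)) v <- ref(remap(v$ref))
      key <- paste0(a$property, "\r", value_key(v))
      if (!key %in% tgt$akeys) {
        tgt$assertions[[length(tgt$assertions) + 1L]] <-
          list(property = a$property, value = v)
        tgt$akeys <- c(tgt$akeys, key)
      }
    }
    new_instances[[target]] <- tgt
  }
  graph$instances <- new_instances
  validate_graph(graph)
  attr(graph, "canonical") <- canon
  invisible(graph)
}

#' Restrict a core graph to one organism
#'
#' Removes protein instances whose asserted taxon id differs from the target
#' taxon, together with participant roles and processes left dangling by
#' their removal.  Instances carrying no taxon id at all are retained with a
#' warning (absence of evidence is not treated as a mismatch).
#'
#' @param graph An `InstanceGraph`, mutated in place.
#' @param taxon Target taxon id (character or integer), e.g. `4932`.
#' @param protein_class Class whose instances are screened.
#' @return `list(removed = <ids removed>, kept_without_taxon = <ids kept
#'   despite missing taxon>)`, invisibly; the graph is modified in place.
#' @export
restrict_organism <- function(graph, taxon, protein_class = "tuo:Protein") {
  taxon <- as.character(taxon)
  removed <- character()
  kept_untagged <- character()
  for (id in instances_of(graph, protein_class)) {
    tx <- assertion_values(graph, id, "tuo:taxonId")
    if (!length(tx)) {
      kept_untagged <- c(kept_untagged, id)
    } else if (!taxon %in% tx) {
      removed <- c(removed, id)
    }
  }
  if (length(kept_untagged)) {
    warning(sprintf("retaining %d protein instance(s) with no taxon id: %s",
                    length(kept_untagged), paste(kept_untagged, collapse = ", ")))
  }
  # cascade: roles played by removed proteins, then processes whose
  # participants were removed
  repeat {
    dangling <- character()
    for (id in setdiff(names(graph$instances), removed)) {
      inst <- graph$instances[[id]]
      for (a in inst$assertions) {
        if (is_ref(a$value) && a$value$ref %in% removed &&
            a$property %in% c("tuo:playedBy", "tuo:hasParticipant")) {
          dangling <- c(dangling, id)
          break
        }
      }
    }
    if (!length(dangling)) break
    removed <- c(removed, dangling)
  }
  graph$instances[removed] <- NULL
  # strip remaining assertions that reference removed instances (e.g. plays
  # links from retained proteins to removed roles)
  for (id in names(graph$instances)) {
    inst <- graph$instances[[id]]
    keep <- vapply(inst$assertions, function(a) {
      !(is_ref(a$value) && !is.null(a$value$ref) && a$value$ref %in% removed)
    }, logical(1))
    if (!all(keep)) {
      inst$assertions <- inst$assertions[keep]
      inst$akeys <- inst$akeys[keep]
      graph$instances[[id]] <- inst
    }
  }
  validate_graph(graph)
  invisible(list(removed = removed, kept_without_taxon = kept_untagged))
}
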
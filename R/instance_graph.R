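# In-memory ontology-instance store: the shared substrate for syntactic and
# core ontologies.  A graph holds a class hierarchy, property definitions and
# typed instances with property assertions; instances keep per-source
# provenance.  Mutable by design (environment-backed), since forward chaining
# repeatedly asserts into the same graph.

#' Create an empty instance graph
#'
#' An instance graph is the common representation used for both syntactic
#' ontologies (mirroring a data format's structure) and the core domain
#' ontology.  It stores named classes with single- or multiple-parent
#' subsumption, object/data property definitions, and instances carrying
#' class memberships, provenance labels and (property, value) assertions.
#' Iteration order over classes, properties, instances and assertions is
#' insertion order, which makes every downstream computation deterministic.
#'
#' @return An object of class `InstanceGraph` (environment-backed, mutable).
#' @export
instance_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$classes <- list()     # name -> list(name, parents)
  g$properties <- list()  # name -> list(name, kind, domain, range)
  g$instances <- list()   # id -> list(id, classes, source, assertions, akeys)
  class(g) <- "InstanceGraph"
  g
}

#' @export
print.InstanceGraph <- function(x, ...) {
  cat(sprintf(
    "<InstanceGraph: %d classes, %d properties, %d instances>\n",
    length(x$classes), length(x$properties), length(x$instances)
  ))
  invisible(x)
}

#' Literal and reference value constructors
#'
#' Assertion values are either references to other instances (for object
#' properties) or literals with a text payload plus a kind tag.
#'
#' @param id Instance identifier to reference.
#' @param value Literal payload (coerced to character).
#' @param kind Literal kind tag, one of `"text"`, `"integer"`, `"decimal"`,
#'   `"boolean"`.
#' @return A value object for use with [add_assertion()].
#' @export
ref <- function(id) {
  stopifnot(is.character(id), length(id) == 1L)
  structure(list(ref = id), class = "rbm_ref")
}

#' @rdname ref
#' @export
lit <- function(value, kind = "text") {
  kind <- match.arg(kind, c("text", "integer", "decimal", "boolean"))
  structure(list(value = as.character(value), kind = kind), class = "rbm_lit")
}

is_ref <- function(x) inherits(x, "rbm_ref")
is_lit <- function(x) inherits(x, "rbm_lit")

value_key <- function(v) {
  if (is_ref(v)) paste0("R\r", v$ref) else paste0("L\r", v$kind, "\r", v$value)
}

#' Add a class to a graph
#'
#' @param graph An `InstanceGraph`.
#' @param name Class identifier (unique within the graph).
#' @param parents Character vector of parent class identifiers; each must
#'   already exist.  Cycles in the parent relation are rejected.
#' @return The graph, invisibly.
#' @export
add_class <- function(graph, name, parents = character()) {
  stopifnot(inherits(graph, "InstanceGraph"), is.character(name), length(name) == 1L)
  if (!is.null(graph$classes[[name]])) {
    existing <- graph$classes[[name]]
    if (!setequal(existing$parents, parents)) {
      stop(sprintf("class '%s' already defined with different parents", name))
    }
    return(invisible(graph))
  }
  missing <- setdiff(parents, names(graph$classes))
  if (length(missing)) {
    stop(sprintf("unknown parent class(es): %s", paste(missing, collapse = ", ")))
  }
  graph$classes[[name]] <- list(name = name, parents = unique(parents))
  # parents must pre-exist, so a cycle cannot be introduced; keep the guard
  # anyway for graphs built by merging.
  if (name %in% class_ancestors(graph, name, strict = TRUE)) {
    graph$classes[[name]] <- NULL
    stop(sprintf("class '%s' would create a cycle in the parent relation", name))
  }
  invisible(graph)
}

#' Add a property definition to a graph
#'
#' @param graph An `InstanceGraph`.
#' @param name Property identifier (unique within the graph).
#' @param kind `"object"` (values are instance references) or `"data"`
#'   (values are literals).
#' @param domain Optional class identifier constraining the subject.
#' @param range Optional class identifier (object) or literal kind (data).
#' @return The graph, invisibly.
#' @export
add_property <- function(graph, name, kind = c("object", "data"),
                         domain = NULL, range = NULL) {
  stopifnot(inherits(graph, "InstanceGraph"), is.character(name), length(name) == 1L)
  kind <- match.arg(kind)
  if (!is.null(graph$properties[[name]])) {
    existing <- graph$properties[[name]]
    if (!identical(existing$kind, kind) ||
        !identical(existing$domain, domain) || !identical(existing$range, range)) {
      stop(sprintf("property '%s' already defined differently", name))
    }
    return(invisible(graph))
  }
  graph$properties[[name]] <- list(name = name, kind = kind,
                                   domain = domain, range = range)
  invisible(graph)
}

#' Add an instance to a graph
#'
#' @param graph An `InstanceGraph`.
#' @param id Instance identifier, unique within the graph.  By convention ids
#'   are namespaced as `<source-namespace>#<local-id>` so instances from
#'   different sources can never collide under [graph_union()].
#' @param classes Character vector of asserted class identifiers.
#' @param source Provenance label(s), e.g. `"UniProtKB"`.
#' @return The graph, invisibly.
#' @export
add_instance <- function(graph, id, classes = character(), source = "unknown") {
  stopifnot(inherits(graph, "InstanceGraph"), is.character(id), length(id) == 1L)
  if (!is.null(graph$instances[[id]])) {
    stop(sprintf("instance id '%s' already present", id))
  }
  missing <- setdiff(classes, names(graph$classes))
  if (length(missing)) {
    stop(sprintf("unknown class(es) for instance '%s': %s",
                 id, paste(missing, collapse = ", ")))
  }
  graph$instances[[id]] <- list(id = id, classes = unique(classes),
                                source = source, assertions = list(),
                                akeys = character())
  invisible(graph)
}

#' Assert class membership on an existing instance
#'
#' @inheritParams add_instance
#' @param cls Class identifier to add.
#' @return `TRUE` if the membership was new, `FALSE` if already present.
#' @export
assert_class <- function(graph, id, cls) {
  inst <- graph$instances[[id]]
  if (is.null(inst)) stop(sprintf("unknown instance '%s'", id))
  if (is.null(graph$classes[[cls]])) stop(sprintf("unknown class '%s'", cls))
  if (cls %in% inst$classes) return(invisible(FALSE))
  inst$classes <- c(inst$classes, cls)
  graph$instances[[id]] <- inst
  invisible(TRUE)
}

#' Add a (property, value) assertion to an instance
#'
#' All properties are multi-valued; asserting an already-present
#' (property, value) pair is a no-op (set semantics), which is what makes
#' forward chaining idempotent.
#'
#' @inheritParams add_instance
#' @param property Property identifier (must be defined in the graph).
#' @param value For object properties, an instance id (character) or [ref()];
#'   for data properties, a character literal or [lit()].
#' @return `TRUE` if the assertion was new, `FALSE` if already present.
#' @export
add_assertion <- function(graph, id, property, value) {
  inst <- graph$instances[[id]]
  if (is.null(inst)) stop(sprintf("unknown instance '%s'", id))
  pdef <- graph$properties[[property]]
  if (is.null(pdef)) stop(sprintf("unknown property '%s'", property))
  if (is.character(value)) {
    value <- if (pdef$kind == "object") ref(value) else lit(value)
  }
  if (pdef$kind == "object") {
    if (!is_ref(value)) stop(sprintf("object property '%s' needs an instance reference", property))
    if (is.null(graph$instances[[value$ref]])) {
      stop(sprintf("object property '%s' on '%s' references unknown instance '%s'",
                   property, id, value$ref))
    }
  } else if (!is_lit(value)) {
    stop(sprintf("data property '%s' needs a literal value", property))
  }
  key <- paste0(property, "\r", value_key(value))
  if (key %in% inst$akeys) return(invisible(FALSE))
  inst$assertions[[length(inst$assertions) + 1L]] <-
    list(property = property, value = value)
  inst$akeys <- c(inst$akeys, key)
  graph$instances[[id]] <- inst
  invisible(TRUE)
}

#' Retrieve an instance by id
#' @inheritParams add_instance
#' @return The instance record (a list), or error if absent.
#' @export
get_instance <- function(graph, id) {
  inst <- graph$instances[[id]]
  if (is.null(inst)) stop(sprintf("unknown instance '%s'", id))
  inst
}

has_instance <- function(graph, id) !is.null(graph$instances[[id]])

#' Assertion values of a property on an instance
#'
#' @inheritParams add_instance
#' @param property Property identifier.
#' @return For data properties a character vector of literal payloads, for
#'   object properties a character vector of referenced instance ids.
#' @export
assertion_values <- function(graph, id, property) {
  inst <- get_instance(graph, id)
  vals <- character()
  for (a in inst$assertions) {
    if (a$property == property) {
      vals <- c(vals, if (is_ref(a$value)) a$value$ref else a$value$value)
    }
  }
  vals
}

#' Class ancestry helpers
#'
#' `class_ancestors()` returns the class and all its (transitive) parents;
#' `class_descendants()` the class and everything below it.
#'
#' @inheritParams add_class
#' @param strict Drop the class itself from the result.
#' @return Character vector of class identifiers.
#' @export
class_ancestors <- function(graph, name, strict = FALSE) {
  if (is.null(graph$classes[[name]])) stop(sprintf("unknown class '%s'", name))
  seen <- character()
  frontier <- graph$classes[[name]]$parents
  while (length(frontier)) {
    nxt <- frontier[[1L]]
    frontier <- frontier[-1L]
    if (nxt %in% seen) next
    seen <- c(seen, nxt)
    frontier <- c(frontier, graph$classes[[nxt]]$parents)
  }
  if (strict) seen else unique(c(name, seen))
}

#' @rdname class_ancestors
#' @export
class_descendants <- function(graph, name, strict = FALSE) {
  if (is.null(graph$classes[[name]])) stop(sprintf("unknown class '%s'", name))
  out <- character()
  for (cls in names(graph$classes)) {
    if (cls != name && name %in% class_ancestors(graph, cls)) out <- c(out, cls)
  }
  if (strict) out else c(name, out)
}

#' Instances asserted in a class or any descendant
#'
#' Subsumption closure is applied: an instance asserted in a subclass is
#' returned for every ancestor class.
#'
#' @inheritParams add_class
#' @param cls Class identifier.
#' @return Character vector of instance ids, in graph insertion order.
#' @export
instances_of <- function(graph, cls) {
  wanted <- class_descendants(graph, cls)
  ids <- character()
  for (inst in graph$instances) {
    if (any(inst$classes %in% wanted)) ids <- c(ids, inst$id)
  }
  ids
}

#' Union of instance graphs
#'
#' Classes and properties that collide across inputs must have identical
#' definitions; instance ids must be disjoint (guaranteed when ids are
#' namespaced by source).  Provenance labels are preserved.
#'
#' @param graphs A list of `InstanceGraph` objects.
#' @return A new `InstanceGraph` containing everything from every input.
#' @export
graph_union <- function(graphs) {
  out <- instance_graph()
  seen_cls <- list()
  seen_prop <- list()
  for (g in graphs) {
    stopifnot(inherits(g, "InstanceGraph"))
    for (cls in g$classes) {
      ex <- seen_cls[[cls$name]]
      if (!is.null(ex) && !setequal(ex, cls$parents)) {
        stop(sprintf("schema conflict: class '%s' defined differently across graphs",
                     cls$name))
      }
      seen_cls[[cls$name]] <- cls$parents
    }
    for (p in g$properties) {
      ex <- seen_prop[[p$name]]
      if (!is.null(ex) && (!identical(ex$kind, p$kind) ||
                           !identical(ex$domain, p$domain) ||
                           !identical(ex$range, p$range))) {
        stop(sprintf("schema conflict: property '%s' defined differently across graphs",
                     p$name))
      }
      seen_prop[[p$name]] <- p
    }
  }
  # two passes per graph so that parent classes exist before children are added
  for (g in graphs) {
    remaining <- names(g$classes)
    while (length(remaining)) {
      progressed <- FALSE
      for (nm in remaining) {
        cls <- g$classes[[nm]]
        if (all(cls$parents %in% names(out$classes))) {
          add_class(out, nm, cls$parents)
          remaining <- setdiff(remaining, nm)
          progressed <- TRUE
        }
      }
      if (!progressed) stop("unresolvable class hierarchy in union input")
    }
    for (p in g$properties) add_property(out, p$name, p$kind, p$domain, p$range)
  }
  for (g in graphs) {
    for (inst in g$instances) {
      if (!is.null(out$instances[[inst$id]])) {
        stop(sprintf("instance id collision in union: '%s'", inst$id))
      }
      out$instances[[inst$id]] <- inst
    }
  }
  validate_graph(out)
  out
}

#' Deep-copy an instance graph
#' @inheritParams add_class
#' @return An independent copy.
#' @export
clone_graph <- function(graph) {
  out <- instance_graph()
  out$classes <- graph$classes
  out$properties <- graph$properties
  out$instances <- graph$instances
  out
}

#' Validate referential integrity of a graph
#'
#' Walks every class, property and instance and checks that all references
#' resolve, the class hierarchy is acyclic and every asserted value is
#' well-formed.  Errors on the first violation.
#'
#' @inheritParams add_class
#' @return `TRUE`, invisibly, when the graph is consistent.
#' @export
validate_graph <- function(graph) {
  for (cls in graph$classes) {
    missing <- setdiff(cls$parents, names(graph$classes))
    if (length(missing)) {
      stop(sprintf("class '%s' has unresolved parent(s): %s",
                   cls$name, paste(missing, collapse = ", ")))
    }
    anc <- class_ancestors(graph, cls$name, strict = TRUE)
    if (cls$name %in% anc) stop(sprintf("cycle through class '%s'", cls$name))
  }
  for (inst in graph$instances) {
    missing <- setdiff(inst$classes, names(graph$classes))
    if (length(missing)) {
      stop(sprintf("instance '%s' asserted in unknown class(es): %s",
                   inst$id, paste(missing, collapse = ", ")))
    }
    for (a in inst$assertions) {
      pdef <- graph$properties[[a$property]]
      if (is.null(pdef)) {
        stop(sprintf("instance '%s' uses unknown property '%s'", inst$id, a$property))
      }
      if (pdef$kind == "object") {
        if (!is_ref(a$value) || is.null(graph$instances[[a$value$ref]])) {
          stop(sprintf("instance '%s': object property '%s' has dangling value",
                       inst$id, a$property))
        }
      } else if (!is_lit(a$value)) {
        stop(sprintf("instance '%s': data property '%s' has non-literal value",
                     inst$id, a$property))
      }
    }
  }
  invisible(TRUE)
}

#' Count all (instance, property, value) assertions in a graph
#' @inheritParams add_class
#' @return Integer count.
#' @export
assertion_count <- function(graph) {
  sum(vapply(graph$instances, function(i) length(i$assertions), integer(1)))
}
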
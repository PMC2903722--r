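# Generic XML -> syntactic-ontology conversion.  The schema is induced from
# the element structure of instance documents: one class per element tag, one
# data property per attribute name (plus one for text content), one object
# property per parent->child tag pair.  Instances then represent the data
# itself, one per element occurrence, in document order.

#' XML-to-ontology mapping convention
#'
#' Controls how tag and attribute names become class and property names.
#' Element tags map to CamelCase class names, attributes to `has`-prefixed
#' CamelCase data properties, child nesting to `has`-prefixed object
#' properties, and direct text content to a single data property
#' (`hasValue` by default).  An optional prefix namespaces all generated
#' names (e.g. `"up:"`), which keeps syntactic schemas from different
#' formats disjoint under graph union.
#'
#' @param prefix Name prefix for every generated class/property name.
#' @param text_property Local name of the text-content data property.
#' @return A convention object.
#' @export
xml_mapping_convention <- function(prefix = "", text_property = "hasValue") {
  structure(list(prefix = prefix, text_property = text_property),
            class = "XmlMappingConvention")
}

camel_case <- function(x) {
  parts <- strsplit(x, "[-_.]")[[1]]
  parts <- parts[nzchar(parts)]
  paste(vapply(parts, function(p) {
    paste0(toupper(substr(p, 1, 1)), substr(p, 2, nchar(p)))
  }, character(1)), collapse = "")
}

conv_class_name <- function(conv, tag) paste0(conv$prefix, camel_case(tag))
conv_attr_property <- function(conv, attr) paste0(conv$prefix, "has", camel_case(attr))
conv_child_property <- function(conv, tag) paste0(conv$prefix, "has", camel_case(tag))
conv_text_property <- function(conv) paste0(conv$prefix, conv$text_property)

local_tag <- function(node) {
  nm <- xml2::xml_name(node)
  sub("^.*:", "", nm)
}

# direct (non-recursive) trimmed text of an element
direct_text <- function(node) {
  kids <- xml2::xml_contents(node)
  txt <- kids[xml2::xml_type(kids) %in% c("text", "cdata")]
  trimws(paste(vapply(txt, xml2::xml_text, character(1)), collapse = ""))
}

element_children <- function(node) {
  kids <- xml2::xml_children(node)
  kids[xml2::xml_type(kids) == "element"]
}

read_xml_doc <- function(doc) {
  if (inherits(doc, "xml_document") || inherits(doc, "xml_node")) return(doc)
  tryCatch(xml2::read_xml(doc), error = function(e) {
    stop(sprintf("malformed XML in '%s': %s", doc, conditionMessage(e)))
  })
}

walk_elements <- function(node, fn, parent = NULL) {
  fn(node, parent)
  for (child in element_children(node)) walk_elements(child, fn, node)
  invisible(NULL)
}

#' Derive a syntactic-ontology schema from an XML document
#'
#' Produces a schema-only instance graph: one class per distinct element tag,
#' one data property per distinct attribute name plus one for element text
#' content, and one object property per distinct parent-child tag pair.
#' Namespace prefixes on tags are stripped to local names first.
#'
#' @param doc An XML file path, XML text, or parsed `xml2` document.
#' @param conv An [xml_mapping_convention()].
#' @return An `InstanceGraph` with classes and properties only.
#' @export
derive_schema <- function(doc, conv = xml_mapping_convention()) {
  doc <- read_xml_doc(doc)
  g <- instance_graph()
  tag_for_class <- character()  # injectivity check: class name -> tag
  ensure_class <- function(tag) {
    cname <- conv_class_name(conv, tag)
    prev <- if (cname %in% names(tag_for_class)) tag_for_class[[cname]] else NULL
    if (!is.null(prev) && prev != tag) {
      stop(sprintf("naming convention is not injective: tags '%s' and '%s' both map to class '%s'",
                   prev, tag, cname))
    }
    tag_for_class[[cname]] <<- tag
    add_class(g, cname)
    cname
  }
  walk_elements(xml2::xml_root(doc), function(node, parent) {
    tag <- local_tag(node)
    ensure_class(tag)
    for (attr in names(xml2::xml_attrs(node))) {
      attr <- sub("^.*:", "", attr)
      if (attr == "") next
      add_property(g, conv_attr_property(conv, attr), "data")
    }
    if (nzchar(direct_text(node))) {
      add_property(g, conv_text_property(conv), "data")
    }
    if (!is.null(parent)) {
      add_property(g, conv_child_property(conv, tag), "object")
    }
  })
  g
}

#' Populate a syntactic ontology with a document's data
#'
#' Creates one instance per element occurrence (asserted in its tag's class),
#' data-property assertions for attributes and non-empty direct text, and
#' object-property assertions for parent-child links.  Instances iterate in
#' document order and every instance carries the source label.
#'
#' @inheritParams derive_schema
#' @param schema Schema graph from [derive_schema()] (or a pinned schema
#'   covering the document's tag vocabulary).  Mutated in place; pass a
#'   [clone_graph()] copy to keep the schema pristine.
#' @param source_label Provenance label stamped on every instance.
#' @param mode `"strict"` errors on tags absent from the schema; `"lenient"`
#'   adds missing classes/properties on the fly.
#' @param namespace Namespace used to mint instance ids
#'   (`<namespace>#<tag>.<counter>`); defaults to the source label.
#' @return The populated graph (same object as `schema`).
#' @export
populate <- function(doc, schema, conv = xml_mapping_convention(),
                     source_label = "unknown", mode = c("strict", "lenient"),
                     namespace = source_label) {
  doc <- read_xml_doc(doc)
  mode <- match.arg(mode)
  g <- schema
  counter <- new.env(parent = emptyenv())
  next_id <- function(tag) {
    n <- (if (exists(tag, envir = counter, inherits = FALSE)) counter[[tag]] else 0L) + 1L
    counter[[tag]] <- n
    sprintf("%s#%s.%d", namespace, tag, n)
  }
  ensure <- function(kind, name, pkind = NULL) {
    present <- if (kind == "class") !is.null(g$classes[[name]]) else !is.null(g$properties[[name]])
    if (present) return(invisible(NULL))
    if (mode == "strict") {
      stop(sprintf("%s '%s' absent from schema (strict mode)", kind, name))
    }
    if (kind == "class") add_class(g, name) else add_property(g, name, pkind)
  }
  populate_node <- function(node) {
    tag <- local_tag(node)
    cname <- conv_class_name(conv, tag)
    ensure("class", cname)
    id <- next_id(tag)
    add_instance(g, id, cname, source_label)
    attrs <- xml2::xml_attrs(node)
    for (attr in names(attrs)) {
      local <- sub("^.*:", "", attr)
      if (local == "") next
      pname <- conv_attr_property(conv, local)
      ensure("property", pname, "data")
      add_assertion(g, id, pname, lit(attrs[[attr]]))
    }
    txt <- direct_text(node)
    if (nzchar(txt)) {
      pname <- conv_text_property(conv)
      ensure("property", pname, "data")
      add_assertion(g, id, pname, lit(txt))
    }
    for (child in element_children(node)) {
      child_id <- populate_node(child)
      pname <- conv_child_property(conv, local_tag(child))
      ensure("property", pname, "object")
      add_assertion(g, id, pname, ref(child_id))
    }
    id
  }
  populate_node(xml2::xml_root(doc))
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
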
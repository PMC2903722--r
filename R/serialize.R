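# RDF serialization of instance graphs (Turtle and RDF/XML) with
# deterministic triple ordering.  Used for debugging, audit artifacts of the
# pipeline, and the graph digest behind the select-purity contract.

RBM_NS <- list(
  cls  = "urn:rbm:class:",
  prop = "urn:rbm:prop:",
  inst = "urn:rbm:inst:",
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#"
)

# URN-safe encoding of local names (ids may contain '#', spaces never occur)
iri_encode <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub("#", "%23", x, fixed = TRUE)
  x <- gsub(" ", "%20", x, fixed = TRUE)
  x <- gsub("<", "%3C", x, fixed = TRUE)
  x <- gsub(">", "%3E", x, fixed = TRUE)
  x <- gsub('"', "%22", x, fixed = TRUE)
  x
}

ttl_escape <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub('"', '\\"', x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x
}

graph_triples <- function(graph) {
  rows <- list()
  add <- function(s, p, o) rows[[length(rows) + 1L]] <<- c(s, p, o)
  rdf_type <- paste0("<", RBM_NS$rdf, "type>")
  rdfs_sub <- paste0("<", RBM_NS$rdfs, "subClassOf>")
  rdfs_class <- paste0("<", RBM_NS$rdfs, "Class>")
  for (cls in graph$classes) {
    s <- paste0("<", RBM_NS$cls, iri_encode(cls$name), ">")
    add(s, rdf_type, rdfs_class)
    for (p in cls$parents) {
      add(s, rdfs_sub, paste0("<", RBM_NS$cls, iri_encode(p), ">"))
    }
  }
  for (inst in graph$instances) {
    s <- paste0("<", RBM_NS$inst, iri_encode(inst$id), ">")
    for (cls in inst$classes) {
      add(s, rdf_type, paste0("<", RBM_NS$cls, iri_encode(cls), ">"))
    }
    for (a in inst$assertions) {
      p <- paste0("<", RBM_NS$prop, iri_encode(a$property), ">")
      o <- if (is_ref(a$value)) {
        paste0("<", RBM_NS$inst, iri_encode(a$value$ref), ">")
      } else {
        paste0('"', ttl_escape(a$value$value), '"')
      }
      add(s, p, o)
    }
  }
  rows
}

#' Serialize an instance graph to Turtle
#'
#' Emits one triple per class definition, subclass link, class membership and
#' property assertion, in graph insertion order, so identical graphs always
#' serialize to identical bytes.
#'
#' @param graph An `InstanceGraph`.
#' @param path Output file path; when `NULL` the Turtle text is returned.
#' @return The Turtle text (invisibly when written to a file).
#' @export
write_turtle <- function(graph, path = NULL) {
  triples <- graph_triples(graph)
  lines <- vapply(triples, function(t) paste(t[1], t[2], t[3], "."), character(1))
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(text, path, sep = "")
  invisible(text)
}

#' Serialize an instance graph to RDF/XML
#'
#' @inheritParams write_turtle
#' @return The RDF/XML text (invisibly when written to a file).
#' @export
write_rdfxml <- function(graph, path = NULL) {
  triples <- graph_triples(graph)
  strip <- function(x) substr(x, 2L, nchar(x) - 1L)
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf("<rdf:RDF xmlns:rdf=\"%s\">", RBM_NS$rdf)
  )
  # group consecutive triples by subject for readability; order preserved
  by_subject <- list()
  subj_order <- character()
  for (t in triples) {
    s <- t[1]
    if (is.null(by_subject[[s]])) {
      by_subject[[s]] <- list()
      subj_order <- c(subj_order, s)
    }
    by_subject[[s]][[length(by_subject[[s]]) + 1L]] <- t
  }
  for (s in subj_order) {
    out <- c(out, sprintf("  <rdf:Description rdf:about=\"%s\">", strip(s)))
    for (t in by_subject[[s]]) {
      pred <- strip(t[2])
      o <- t[3]
      if (startsWith(o, "<")) {
        out <- c(out, sprintf("    <rbm:p rdf:resource=\"%s\" rbm:pred=\"%s\" xmlns:rbm=\"urn:rbm:\"/>",
                              strip(o), xml_escape(pred)))
      } else {
        litval <- substr(o, 2L, nchar(o) - 1L)
        out <- c(out, sprintf("    <rbm:p rbm:pred=\"%s\" xmlns:rbm=\"urn:rbm:\">%s</rbm:p>",
                              xml_escape(pred), xml_escape(litval)))
      }
    }
    out <- c(out, "  </rdf:Description>")
  }
  out <- c(out, "</rdf:RDF>")
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(text, path, sep = "")
  invisible(text)
}

#' Deterministic digest of a graph's content
#'
#' Two graphs with identical classes, properties, instances and assertions
#' (in the same order) have equal digests.  Used to check the
#' non-materializing contract of select queries.
#'
#' @param graph An `InstanceGraph`.
#' @return A character scalar.
#' @export
graph_digest <- function(graph) {
  txt <- write_turtle(graph)
  # rolling polynomial hash over the serialized bytes (mod a Mersenne
  # prime); the digest only needs equality semantics
  bytes <- utf8ToInt(txt)
  mod <- 2147483647
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% mod
  sprintf("%d-%d", h, nchar(txt))
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub('"', "&quot;", x, fixed = TRUE)
  x
}
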
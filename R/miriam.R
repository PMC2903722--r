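# MIRIAM cross-reference URIs.  Annotations are rendered as URNs of the form
# urn:miriam:<datatype>:<id> (the scheme in use when URN-style MIRIAM
# annotations were standard practice); an identifiers.org URL form can be
# selected instead.  The registry mapping database names, as they appear in
# source records, to URN datatype tokens ships as editable YAML config.

MIRIAM_QUALIFIERS <- c(
  "is", "isVersionOf", "hasVersion", "isDescribedBy", "hasPart", "isPartOf",
  "isHomologTo", "isEncodedBy", "encodes", "occursIn", "hasProperty",
  "isPropertyOf"
)

#' Load the MIRIAM database registry
#'
#' The registry is YAML mapping each URN datatype token to the database-name
#' spellings that should resolve to it (matched case-insensitively after
#' whitespace trimming).
#'
#' @param path Registry file; defaults to the registry shipped with the
#'   package.
#' @return A named character vector: normalized database name -> token.
#' @export
load_miriam_registry <- function(path = system.file("extdata", "miriam_registry.yaml",
                                                    package = "rbmed")) {
  spec <- yaml::read_yaml(path)
  out <- character()
  for (token in names(spec)) {
    for (alias in spec[[token]]) {
      out[[tolower(trimws(alias))]] <- token
    }
  }
  out
}

miriam_token <- function(db, registry) {
  key <- tolower(trimws(db))
  if (key %in% names(registry)) registry[[key]] else NA_character_
}

percent_encode <- function(x) {
  utils::URLencode(x, reserved = TRUE)
}

#' Build a MIRIAM URI for a database record
#'
#' @param db Database name as it appears in the source record.
#' @param id Record identifier (percent-encoded in the URI).
#' @param registry Registry from [load_miriam_registry()].
#' @param style `"urn"` for `urn:miriam:<token>:<id>`, `"url"` for
#'   `https://identifiers.org/<token>/<id>`.
#' @return The URI, or `NA_character_` when the database is not registered.
#' @export
miriam_uri <- function(db, id, registry, style = c("urn", "url")) {
  style <- match.arg(style)
  token <- miriam_token(db, registry)
  if (is.na(token)) return(NA_character_)
  if (style == "urn") {
    paste0("urn:miriam:", token, ":", percent_encode(id))
  } else {
    paste0("https://identifiers.org/", token, "/", percent_encode(id))
  }
}

#' Parse a MIRIAM URI back into (datatype, id)
#'
#' @param uri A `urn:miriam:` URN or identifiers.org URL.
#' @return `list(datatype =, id =)` with the id percent-decoded, or `NULL`
#'   when the URI is not MIRIAM-shaped.
#' @export
parse_miriam_uri <- function(uri) {
  if (grepl("^urn:miriam:", uri)) {
    rest <- sub("^urn:miriam:", "", uri)
    i <- regexpr(":", rest, fixed = TRUE)
    if (i < 0) return(NULL)
    datatype <- substr(rest, 1L, i - 1L)
    id <- utils::URLdecode(substr(rest, i + 1L, nchar(rest)))
    if (!nzchar(datatype) || !nzchar(id)) return(NULL)
    return(list(datatype = datatype, id = id))
  }
  if (grepl("^https?://identifiers\\.org/", uri)) {
    rest <- sub("^https?://identifiers\\.org/", "", uri)
    parts <- strsplit(rest, "/", fixed = TRUE)[[1]]
    if (length(parts) < 2L) return(NULL)
    return(list(datatype = parts[[1]],
                id = utils::URLdecode(paste(parts[-1], collapse = "/"))))
  }
  NULL
}

valid_miriam_uri <- function(uri) !is.null(parse_miriam_uri(uri))
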
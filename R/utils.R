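# small shared helpers

# fetch an attribute by local name regardless of namespace prefix
xml_attr_local <- function(node, local) {
  attrs <- xml2::xml_attrs(node)
  hits <- attrs[sub("^.*:", "", names(attrs)) == local]
  if (length(hits)) hits[[1]] else NA_character_
}

is_blank <- function(x) is.null(x) || is.na(x) || !nzchar(x)
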
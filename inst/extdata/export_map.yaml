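# Export configuration: identity cross-references use the bqbiol "is"
# qualifier and URN-style MIRIAM URIs; species mapped to a core Protein
# receive the polypeptide-chain SBO term when they carry none.
qualifier: is
uri_style: urn
sbo_terms:
  tuo:Protein: "SBO:0000252"
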
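# Protein-of-interest classification.  Each rule collects core proteins
# whose synonyms match a checkpoint gene name (case-insensitively) and
# declares them members of the corresponding named protein class.

tuo:Protein(?someEntity) ^ tuo:synonym(?someEntity, ?s) ^
swrlb:containsIgnoreCase(?s, "rad9")
  -> tuo:Rad9(?someEntity)

tuo:Protein(?someEntity) ^ tuo:synonym(?someEntity, ?s) ^
swrlb:containsIgnoreCase(?s, "rad53")
  -> tuo:Rad53(?someEntity)

tuo:Protein(?someEntity) ^ tuo:synonym(?someEntity, ?s) ^
swrlb:containsIgnoreCase(?s, "chk1")
  -> tuo:Chk1(?someEntity)

tuo:Protein(?someEntity) ^ tuo:synonym(?someEntity, ?s) ^
swrlb:containsIgnoreCase(?s, "mec1")
  -> tuo:Mec1(?someEntity)

tuo:Protein(?someEntity) ^ tuo:synonym(?someEntity, ?s) ^
swrlb:containsIgnoreCase(?s, "rad17")
  -> tuo:Rad17(?someEntity)
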
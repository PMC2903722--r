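# UniProtKB syntactic ontology -> core ontology import rules.
# Every entry is a protein; accessions, names, taxon, entry-level
# cross-references, function text and subcellular location are lifted onto
# core properties.

up:Entry(?e) -> tuo:Protein(?e)

up:Entry(?e) ^ up:hasAccession(?e, ?a) ^ up:hasValue(?a, ?v)
  -> tuo:accession(?e, ?v)

up:Entry(?e) ^ up:hasName(?e, ?n) ^ up:hasValue(?n, ?v)
  -> tuo:synonym(?e, ?v)

up:Entry(?e) ^ up:hasProtein(?e, ?p) ^ up:hasRecommendedName(?p, ?r) ^
up:hasFullName(?r, ?f) ^ up:hasValue(?f, ?v)
  -> tuo:primaryName(?e, ?v) ^ tuo:synonym(?e, ?v)

up:Entry(?e) ^ up:hasProtein(?e, ?p) ^ up:hasAlternativeName(?p, ?r) ^
up:hasFullName(?r, ?f) ^ up:hasValue(?f, ?v)
  -> tuo:synonym(?e, ?v)

up:Entry(?e) ^ up:hasGene(?e, ?g) ^ up:hasName(?g, ?n) ^ up:hasValue(?n, ?v)
  -> tuo:synonym(?e, ?v)

up:Entry(?e) ^ up:hasOrganism(?e, ?o) ^ up:hasDbReference(?o, ?d) ^
up:hasType(?d, "NCBI Taxonomy") ^ up:hasId(?d, ?t)
  -> tuo:taxonId(?e, ?t)

up:Entry(?e) ^ up:hasDbReference(?e, ?x) ^ up:hasType(?x, ?db) ^ up:hasId(?x, ?id)
  -> tuo:CrossReference(?x) ^ tuo:hasCrossReference(?e, ?x) ^
     tuo:databaseName(?x, ?db) ^ tuo:databaseId(?x, ?id)

up:Entry(?e) ^ up:hasComment(?e, ?c) ^ up:hasType(?c, "function") ^
up:hasText(?c, ?t) ^ up:hasValue(?t, ?v)
  -> tuo:functionNote(?e, ?v)

up:Entry(?e) ^ up:hasComment(?e, ?c) ^ up:hasSubcellularLocation(?c, ?sl) ^
up:hasLocation(?sl, ?l) ^ up:hasValue(?l, ?v)
  -> tuo:subcellularLocation(?e, ?v)
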
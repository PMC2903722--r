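# BioPAX (level-2 style) -> core ontology import rules.
# BioPAX distinguishes the protein (physicalEntity) from its participant
# occurrences (physicalEntityParticipant); the same dichotomy exists in the
# core ontology as Protein vs ParticipantRole, so the mapping is direct.

bp:protein(?p) -> tuo:Protein(?p)

bp:protein(?p) ^ bp:NAME(?p, ?v) -> tuo:primaryName(?p, ?v) ^ tuo:synonym(?p, ?v)

bp:protein(?p) ^ bp:SHORT-NAME(?p, ?v) -> tuo:synonym(?p, ?v)

bp:protein(?p) ^ bp:SYNONYMS(?p, ?v) -> tuo:synonym(?p, ?v)

bp:protein(?p) ^ bp:XREF(?p, ?x) ^ bp:DB(?x, "UniProtKB") ^ bp:ID(?x, ?id)
  -> tuo:accession(?p, ?id)

bp:protein(?p) ^ bp:XREF(?p, ?x) ^ bp:DB(?x, ?db) ^ bp:ID(?x, ?id)
  -> tuo:CrossReference(?x) ^ tuo:hasCrossReference(?p, ?x) ^
     tuo:databaseName(?x, ?db) ^ tuo:databaseId(?x, ?id)

bp:protein(?p) ^ bp:ORGANISM(?p, ?o) ^ bp:TAXON-XREF(?o, ?x) ^ bp:ID(?x, ?t)
  -> tuo:taxonId(?p, ?t)

bp:interaction(?x) -> tuo:Interaction(?x)

bp:interaction(?x) ^ bp:PARTICIPANTS(?x, ?p)
  -> tuo:ParticipantRole(?p) ^ tuo:hasParticipant(?x, ?p)

bp:physicalEntityParticipant(?p) ^ bp:PHYSICAL-ENTITY(?p, ?e)
  -> tuo:playedBy(?p, ?e) ^ tuo:plays(?e, ?p)
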
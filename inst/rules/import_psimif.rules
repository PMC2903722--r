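# PSI-MIF syntactic ontology -> core ontology import rules.
# Interactors become proteins, interactions become processes, and the
# participant plumbing (interactor references resolved by id) becomes
# plays / playedBy role links.

psi:ProteinInteractor(?i) -> tuo:Protein(?i)

psi:ProteinInteractor(?i) ^ psi:hasNames(?i, ?n) ^ psi:hasShortLabel(?n, ?s) ^
psi:hasValue(?s, ?v)
  -> tuo:synonym(?i, ?v)

psi:ProteinInteractor(?i) ^ psi:hasNames(?i, ?n) ^ psi:hasFullName(?n, ?f) ^
psi:hasValue(?f, ?v)
  -> tuo:primaryName(?i, ?v) ^ tuo:synonym(?i, ?v)

psi:ProteinInteractor(?i) ^ psi:hasXref(?i, ?x) ^ psi:hasPrimaryRef(?x, ?r) ^
psi:hasDb(?r, "uniprotkb") ^ psi:hasId(?r, ?id)
  -> tuo:accession(?i, ?id)

psi:ProteinInteractor(?i) ^ psi:hasOrganism(?i, ?o) ^ psi:hasNcbiTaxId(?o, ?t)
  -> tuo:taxonId(?i, ?t)

psi:Interaction(?x) -> tuo:Interaction(?x)

psi:Interaction(?x) ^ psi:hasParticipantList(?x, ?pl) ^
psi:hasProteinParticipant(?pl, ?p)
  -> tuo:ParticipantRole(?p) ^ tuo:hasParticipant(?x, ?p)

psi:ProteinParticipant(?p) ^ psi:hasProteinInteractorRef(?p, ?r) ^
psi:hasRef(?r, ?rid) ^ psi:ProteinInteractor(?i) ^ psi:hasId(?i, ?rid)
  -> tuo:playedBy(?p, ?i) ^ tuo:plays(?i, ?p)
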
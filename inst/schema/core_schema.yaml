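# Core ("telomere") ontology schema: a compact, semantically homogeneous
# model of the yeast DNA-damage-checkpoint domain.  Classes and properties
# are named by biology only -- nothing here refers to any source data
# format.  Defined classes are given by Manchester-style expressions and
# receive their members by classification, not assertion.
classes:
  tuo:Entity: ~
  tuo:Protein: tuo:Entity
  tuo:Rad9: tuo:Protein
  tuo:Rad53: tuo:Protein
  tuo:Chk1: tuo:Protein
  tuo:Mec1: tuo:Protein
  tuo:Rad17: tuo:Protein
  tuo:Process: tuo:Entity
  tuo:Interaction: tuo:Process
  tuo:Rad9Rad53Interaction: tuo:Interaction
  tuo:Rad9Chk1Interaction: tuo:Interaction
  tuo:Rad9Mec1Interaction: tuo:Interaction
  tuo:Rad9Rad17Interaction: tuo:Interaction
  tuo:ParticipantRole: ~
  tuo:Organism: tuo:Entity
  tuo:CrossReference: ~
  tuo:Compartment: tuo:Entity
properties:
  tuo:plays: {kind: object}
  tuo:playedBy: {kind: object}
  tuo:hasParticipant: {kind: object}
  tuo:hasCrossReference: {kind: object}
  tuo:fromOrganism: {kind: object}
  tuo:locatedIn: {kind: object}
  tuo:synonym: {kind: data}
  tuo:primaryName: {kind: data}
  tuo:accession: {kind: data}
  tuo:taxonId: {kind: data}
  tuo:databaseName: {kind: data}
  tuo:databaseId: {kind: data}
  tuo:functionNote: {kind: data}
  tuo:subcellularLocation: {kind: data}
defined_classes:
  tuo:Rad9Rad53Interaction: >-
    tuo:hasParticipant some (tuo:playedBy some tuo:Rad9) and
    tuo:hasParticipant some (tuo:playedBy some tuo:Rad53)
  tuo:Rad9Chk1Interaction: >-
    tuo:hasParticipant some (tuo:playedBy some tuo:Rad9) and
    tuo:hasParticipant some (tuo:playedBy some tuo:Chk1)
  tuo:Rad9Mec1Interaction: >-
    tuo:hasParticipant some (tuo:playedBy some tuo:Rad9) and
    tuo:hasParticipant some (tuo:playedBy some tuo:Mec1)
  tuo:Rad9Rad17Interaction: >-
    tuo:hasParticipant some (tuo:playedBy some tuo:Rad9) and
    tuo:hasParticipant some (tuo:playedBy some tuo:Rad17)
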
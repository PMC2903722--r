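# Display (but never store) every process in which a RAD9 protein
# participates.  Select results are presented to the user; the ontology is
# bit-identical before and after the query.

tuo:Rad9(?rad9instance) ^ tuo:plays(?rad9instance, ?participant) ^
tuo:hasParticipant(?process, ?participant)
  -> sqwrl:select(?rad9instance, ?process)
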
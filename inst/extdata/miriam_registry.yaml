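# MIRIAM URN datatype tokens and the database-name spellings (as they appear
# in source records) that resolve to them.  Matching is case-insensitive.
uniprot: ["UniProtKB", "uniprotkb", "uniprot", "Swiss-Prot"]
intact: ["IntAct"]
sgd: ["SGD"]
pathwaycommons: ["Pathway Commons", "pathwaycommons", "CPATH"]
taxonomy: ["NCBI Taxonomy", "taxonomy"]
biogrid: ["BioGRID"]
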
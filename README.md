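# rbmed — rule-based semantic mediation for SBML model annotation

Quantitative systems-biology models are only as useful as their biological
annotation, yet the knowledge needed to annotate even a small model is
scattered across databases with different formats *and* different semantics:
a protein record in UniProtKB, an interactor in a PSI-MI interaction file
and a `physicalEntity` in a BioPAX pathway document all describe the same
molecule in structurally incompatible ways. `rbmed` implements **rule-based
mediation** for this problem: instead of mapping every format onto every
other, each format is first converted mechanically into a *syntactic
ontology* that mirrors its structure, and antecedent→consequent rules then
*materialise* the data into a single compact, biologically meaningful *core
ontology*. The integrated knowledge is queried there and exported back onto
an SBML Level 2 model as MIRIAM cross-reference annotations, SBO terms,
display names, new species and skeleton reactions.

The package is aimed at modellers and data integrators who want annotation
pipelines that are auditable (every model change is recorded in a replayable
delta), deterministic, and extensible by editing plain-text rule and schema
files rather than code.

## The method

Integration proceeds in four stages:

1. **Syntactic conversion.** XML formats are converted generically: element
   tags become classes, attributes and text content become data properties,
   nesting becomes object properties, and every element occurrence becomes
   an instance (`derive_schema()` / `populate()`, specialised by
   `read_uniprot()` and `read_psimif()`). BioPAX is already an ontology and
   is read natively from RDF (`read_biopax()`).

2. **Rule-based import.** Mapping rules with syntactic-ontology atoms in
   the antecedent and core-ontology atoms in the consequent are applied by
   forward chaining to fixpoint (`apply_rules()`). A typical rule, in the
   package's rule grammar:

   ```
   tuo:Protein(?someEntity) ^ tuo:synonym(?someEntity, ?s) ^
   swrlb:containsIgnoreCase(?s, "rad9") -> tuo:Rad9(?someEntity)
   ```

   Select queries (`sqwrl:select`) display bindings without ever storing
   them back — the graph is bit-identical before and after `run_select()`.

3. **Reconciliation.** Records from different sources that denote one
   real-world protein are found by shared keys (UniProtKB accession, with a
   name+taxon fallback), grouped by transitive closure
   (`assert_equivalences()`), merged into canonical instances that retain
   all provenance (`merge_equivalents()`), and restricted to the organism
   of interest (`restrict_organism()`). Defined classes such as

   ```
   tuo:hasParticipant some (tuo:playedBy some tuo:Rad9) and
   tuo:hasParticipant some (tuo:playedBy some tuo:Rad53)
   ```

   then classify the integrated interactions (`classify_instances()`).

4. **Export.** Mapped species gain one `bqbiol:is` MIRIAM URN
   (`urn:miriam:<datatype>:<id>`) per distinct cross-reference, an SBO term
   and a name where missing (`export_annotations()`); classified
   interactions absent from the model become skeleton reactions — reactants
   only, no kinetics — and unidentified placeholder species are screened
   for candidate identities (`propose_new_reactions()`). Export is strictly
   additive and idempotent.

## Worked example

The packaged corpus generator reproduces the study conditions of the RAD9
checkpoint use cases — five yeast checkpoint proteins across three sources,
a human homolog decoy, and a toy telomere-uncapping model (synthetic) with
two RAD9 species and four RAD9 reactions, two of them with placeholder
partners (`Rad9Kin`, `ExoX`):

```r
library(rbmed)
corpus <- tempfile("corpus")
generate_corpus(corpus)
res <- run_pipeline(file.path(corpus, "pipeline.yaml"))
res$delta
#> <ModelDelta>
#>   annotations_added        18
#>   sbo_terms_added          6
#>   names_added              0
#>   species_added            0
#>   reactions_added          2
#>   interactions_confirmed   2
#>   placeholder_candidates   1
res$delta$candidates[[1]]$reason
#> [1] "'Rad9Kin' acts on DNA damage-dependent checkpoint protein RAD9;
#>      Serine/threonine-protein kinase MEC1 is annotated as a kinase of
#>      that protein"
```

Reading the delta: each of the two RAD9 species gained 5 new MIRIAM
annotations (its sixth, the original UniProtKB reference, was confirmed and
deduplicated) and 1 SBO term; the RAD9–RAD53 and RAD9–CHK1 interactions
were recognised as already present in the model and *not* re-added; two
skeleton reactions (RAD9–MEC1, RAD9–RAD17) were appended for manual
curation; and MEC1 was reported — as a candidate, never substituted — as
the identity of the `Rad9Kin` placeholder. The non-materialising
interaction query shows the single reconciled RAD9 entity participating in
all five source interactions:

```r
q <- parse_rules_file(file.path(corpus, "query_interactions.rules"))[[1]]
run_select(res$graph, q)
#>      rad9instance                       process
#> 1 uniprot#entry.1         biogrid#interaction.1
#> 2 uniprot#entry.1         biogrid#interaction.2
#> 3 uniprot#entry.1         biogrid#interaction.3
#> 4 uniprot#entry.1 pathwaycommons#int_rad9_rad53
#> 5 uniprot#entry.1  pathwaycommons#int_rad9_chk1
```

A command-line driver with `fixtures`, `convert`, `run`, `query` and
`annotate` subcommands ships in `inst/cli/rbmed.R`.

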
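---
title: "Rule-based mediation: design and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based mediation: design and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbmed)
```

## The integration model

`rbmed` integrates heterogeneous molecular-biology records by separating
*syntactic* from *semantic* heterogeneity. Each input format is converted
mechanically into a **syntactic ontology** whose classes mirror the
format's structure — one class per element tag, `has`-prefixed properties
for attributes, text and nesting — and whose instances are the data items
themselves. Nothing biological is asserted at this stage; the conversion
only isolates the format so that the semantics can be handled once, in one
place. That place is the **core ontology**: a compact, format-independent
schema of the domain (proteins, the roles they play in processes,
organisms, cross-references), shipped as an editable YAML file. Mapping
between the two layers is done with **antecedent→consequent rules** whose
antecedents match syntactic atoms and whose consequents assert core-class
memberships and core-property values. Because the data are *materialised*
in the core ontology, downstream querying never needs to know which format
a fact came from, and adding a new source is a new reader plus a new rule
file — the core schema does not change.

The key assumptions of this architecture are worth stating explicitly:

* **Monotonicity.** Rules only add assertions; there is no negation and no
  retraction. This is what makes forward chaining terminate at a fixpoint
  that is independent of rule order, and it matches the expressivity of
  the rule languages this design descends from. Filtering steps that look
  like negation ("which interactions are *not* in the model?") are
  realised downstream as explicit set comparisons against the model, not
  as negation-as-failure inside the engine.
* **Set semantics.** Re-asserting an existing fact is a no-op, so applying
  a rule set twice adds nothing. Rules that mint new individuals
  (`swrlx:makeOWLThing`) are guarded by a (rule id, anchor binding) key:
  re-running such a rule reuses the individual it minted before instead of
  duplicating it. This guard exists because naive individual-creating
  rules are a classic source of silently multiplying instances.
* **Subclass closure, nothing more.** Class atoms and the classifier honor
  the (acyclic, multiple-inheritance) named-class hierarchy. There is no
  general OWL reasoning — no disjointness, cardinality or consistency
  checking — because the method does not need it: defined classes here are
  intersections of existential restrictions over asserted object links.

## The pipeline and its tunable parameters

`run_pipeline()` executes: convert → union → import rules → reconcile →
organism restriction → classify → export → propose reactions → write. The
parameters that matter, their defaults, and why:

* **Reconciliation keys** (`reconciliation_keys`, default
  `accession, name_taxon`). The primary key is a shared UniProtKB
  accession: it is the one identifier all three source types carry, and it
  is what makes automated equivalence safe. The fallback — equal
  case-insensitive primary name *and* equal taxon — catches records that
  lack an accession. Two records sharing a key but carrying different
  taxon ids are *never* merged (a warning is raised): an accession
  collision across organisms indicates dirty data, and merging would
  destroy information irreversibly.
* **Target taxon** (`taxon`, corpus default `4932`, *S. cerevisiae*).
  Protein instances with a conflicting taxon are removed after merging,
  together with roles and processes left dangling. Instances with no taxon
  assertion are retained with a warning — absence of evidence is not
  evidence of a mismatch.
* **Rule round bound** (`max_rounds = 100`). Chaining is monotone over a
  finite assertion universe, so it always terminates; the bound exists as
  a tripwire against pathological rule sets and aborts with a diagnostic
  rather than looping.
* **MIRIAM style** (`uri_style: urn`). Annotations are emitted as
  `urn:miriam:<datatype>:<id>` URNs, the form contemporary with the
  curation practice this package models; `url` switches to
  identifiers.org URLs. The registry mapping database-name spellings to
  datatype tokens is config (`miriam_registry.yaml`) because source
  records spell database names inconsistently.
* **Qualifier** (`qualifier: is`). Identity cross-references use
  `bqbiol:is`, the standard qualifier for "this species is this database
  entity"; it is config-overridable since some curation styles prefer
  `isVersionOf` for protein forms.
* **SBO assignment** (`sbo_terms`). Species mapped to a core `tuo:Protein`
  receive `SBO:0000252` ("polypeptide chain") when they carry no term.
  The toy corpus fixes this value as its reconstruction of a sensible
  protein-species term; it is a config entry, not code.
* **Provenance notes** (`provenance_notes: false`). The standard SBML
  annotation syntax has no slot for *who added* an annotation, so by
  default the output model carries no tool provenance; the audit trail is
  the machine-readable delta instead. Setting the flag writes
  tool/version/date into the model `notes`.

## Species mapping and model extension

A model species maps to a core entity by (a) an existing MIRIAM UniProtKB
annotation matching the entity's accession, else (b) exact
case-insensitive name-to-synonym match. Matching is deliberately strict: a
species matching two canonical entities is an error that names both
candidates, never a silent choice, and fuzzy matching is out of scope
because a wrong annotation is worse than a missing one. Many species may
map to one entity — active and inactive forms of one protein are the
normal case — and that is allowed by construction. The converse (two
records for one concept) is *represented* as two instances unless a key
merges them.

Classified interactions extend the model conservatively. An interaction
between entities A and B is **confirmed** if some existing reaction
already involves species of both — confirmed interactions are recorded and
never re-added. Otherwise a **skeleton reaction** is appended: the two
species as reactants, no products, no kinetic law, no parameters — a
structurally valid placeholder whose biology the modeller must fill in. A
partner with no species at all is added as a new species carrying the
entity's annotations. Finally, unmapped species that *act on* a mapped
species (reactant or modifier in one of its reactions; products are
excluded, being outputs rather than actors) are treated as placeholders
and screened against the newly proposed partners: a partner whose function
annotation describes a kinase of the placeholder's co-reactant, when the
placeholder's own label hints at a kinase ("kin"), is reported as a
*candidate* identity in the delta. The candidate is never substituted into
the model — identification of a placeholder is a provisional, human
decision.

## What the synthetic corpus emulates — and what it does not

`generate_corpus()` writes a deterministic corpus that re-expresses the
documented study conditions: UniProtKB-style entries for the five yeast
checkpoint proteins (P14737/RAD9, P22216/RAD53, P38147/CHK1, P38111/MEC1,
P48581/RAD17), PSI-MI 1.0-style interactions RAD9–RAD53, RAD9–MEC1 and
RAD9–RAD17, BioPAX level-2-style interactions RAD9–RAD53 and RAD9–CHK1,
and a toy SBML model — a synthetic stand-in for the published
telomere-uncapping model, constrained to its documented structure: two
RAD9 species (active/inactive, both annotated with P14737), reactions with
RAD53 and CHK1, placeholder species `Rad9Kin` and `ExoX` each in one RAD9
reaction, and MEC1 and RAD17 present but not in any RAD9 reaction. Two
decoys each test exactly one removal mechanism: a human RAD9 homolog
(shares the `rad9` synonym, removable only by organism restriction) and a
BioGRID-only interactor DBP1 (yeast taxon, removable only by the
classification rules). The split of RAD9's five exportable
cross-references across IntAct, UniProtKB, Pathway Commons and SGD is a
reconstruction (Pathway Commons contributes two), as is the SBO term; the
originals are not on record.

Passing tests on this corpus demonstrate that the *mechanics* —
conversion, chaining, reconciliation, classification, export — behave as
specified end to end. They do not demonstrate robustness to the mess of
real exports: schema-version drift, huge files, records with conflicting
accessions, organisms encoded in free text. The readers parse documented
dialect subsets, not the full official schemas.

## Numerical and representational choices

* Determinism everywhere: iteration follows insertion order, serializations
  (Turtle, RDF/XML, SBML) are byte-stable, and the default corpus uses no
  randomness — identical inputs give identical outputs, which is what makes
  the delta replayable and the pipeline testable by checksum.
* Literals are text with an optional kind tag. None of the integrated
  fields need typed arithmetic, and full typed-literal machinery would buy
  nothing here; taxon ids compare as strings.
* The rule grammar is the plain-text rendering of printed
  antecedent→consequent rules (`Prefix:Name(?var, …)` joined by `^`/`∧`,
  `->`/`→`), not an XML serialization: rules are meant to be reviewed and
  diffed by humans. The builtin `containsIgnoreCase` is also registered
  under the spelling `containslgnoreCase` (lowercase l), which appears in
  printed renderings of such rules.
* Class and property names carry their prefix (`tuo:Protein`, `up:Entry`)
  as part of the name. This keeps syntactic and core schemas disjoint
  under graph union by construction and makes rule text match the printed
  prefixed form exactly.
* The core→SBML export direction is a declarative map (class → SBO term,
  registry of database tokens, qualifier) rather than rule syntax: SBML
  attributes are not property atoms, and a two-column table is the honest
  shape of that mapping.
* SBML handling is a native Level 2 reader/writer over `xml2` with a
  structural validator (identifier uniqueness and well-formedness,
  reference integrity, SBO pattern, MIRIAM URN grammar, qualifier
  vocabulary). It round-trips the attributes and annotation blocks this
  package touches; it is not a full SBML consistency checker and does not
  interpret math, units or events.

## Known limitations

* The core schema covers the classes and properties the checkpoint use
  cases exercise; it is a seed for a domain ontology, not a comprehensive
  one. New use cases extend it by editing the schema file.
* Readers support UniProtKB XML, PSI-MI 1.0 and BioPAX level-2-style
  dialect subsets; PSI-MI 2.5, BioPAX level 3 and UniProt flat files are
  out of scope, as is any network retrieval.
* The rule engine is a conjunctive matcher with builtins: no negation, no
  aggregation, no collection operators in select queries.
* Reconciliation quality is bounded by the keys: records lacking both an
  accession and a (name, taxon) pair stay unmerged by design.
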
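---
title: "Methods: domain-signature screening for vesicle-coat homologs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain-signature screening for vesicle-coat homologs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the method

Cytosolic coated-vesicle traffic runs on three machines — COPII, COPI and
clathrin-coated vesicles (CCV, including the AP1–5 adaptor complexes) — all
recruited by small GTPases (Sar1 or Arf1). Chloroplasts show vesicle-like
transport with bioinformatic support for a COPII-like system, which raises
the question whether COPI- or CCV-like components are present in the
chloroplast proteome as well.

`coatscreen` implements the desk-scale homology screen used to address that
question. It does not align sequences. Instead, each *query* vesicle-coat
subunit protein (from Arabidopsis, yeast, mouse, human, or for the rice
analysis, the corresponding query sets) is reduced to its **domain
signature**: the set of PROSITE (`PS`) and Pfam (`PF`) accessions annotated
on it. A chloroplast-annotated protein is a **candidate** for a subunit iff
its own domain set contains some signature of that subunit (superset
containment). Candidate lists are then annotated with subcellular
localization evidence and classified with a traffic-light scheme.

The pipeline stages mirror the workflow the package reproduces:

1. **Catalog** (`load_query_table()`, `build_catalog()`): one signature per
   query protein. We deliberately do not merge the signatures of orthologous
   queries into a union or intersection per subunit: a yeast subunit and its
   Arabidopsis counterpart can carry different accessions (the screen's
   Arabidopsis AP2 β2 hits come from a yeast-specific carbamoyl-phosphate
   synthase signature that the Arabidopsis cytosolic subunit lacks), and
   keeping per-protein signatures preserves exactly those distinctions.
2. **Screen** (`screen_proteome()`): superset containment, not equality.
   Equality would wrongly reject candidates carrying extra domains, such as
   the rice clathrin heavy chains, which carry one accession beyond the
   heavy-chain signature yet are reported as hits.
3. **Partition**: a locus hitting ≥ 2 distinct subunit identities has
   "commonly occurring" domains (e.g. the Adaptin N-terminal region PF01602
   or the Mu-homology-domain profile PS51072) and is reported in the
   multi-subunit partition. The four Arf groups (ArfA/B/D/B2) are modelled as
   four distinct identities, which is why the four GTPase candidates are
   multi-subunit by construction.
4. **Localization** (`integrate_evidence()`): verdicts annotate and never
   filter — the screen keeps candidates with contradictory evidence in its
   tables, as the underlying analysis did.
5. **Classification** (`classify_locus()`, `classify_identity()`): green /
   yellow for candidate loci, red for subunits with no candidate.

## The PROSITE pattern engine

Pattern-type accessions (`PS0xxxx`) are regular-expression-like motifs, so
they can be assigned from raw FASTA without a web service.
`parse_prosite_pattern()` accepts the standard grammar (`-`-separated
elements, `x` wildcard, `[..]` classes, `{..}` negated classes, `(n)`/`(n,m)`
repeats, `<`/`>` anchors, optional trailing `.`); `scan_sequence()` reports
1-based inclusive coordinates.

Numerical/semantic choices:

* **Per start position, one span** — the leftmost-longest (greedy-repeat)
  expansion. Downstream screening only consumes presence/absence, so span
  multiplicity must be deterministic but need not enumerate every repeat
  expansion. Overlapping starts are all reported.
* **Ambiguous residues** (`X`, and the rarer `B`, `Z`, `U`, `O`) satisfy
  only the wildcard element, never an exact or class element. This is
  conservative: an ambiguous residue can never invent a hit.
* **Profiles are not patterns.** `PS5xxxx` and `PF` accessions are
  position-weight/HMM models; registering a pattern string under them is an
  error. Their assignments enter through the proteome annotation table.
* The "no match span disappears when the sequence grows" invariant is
  checked on match *starts*: under greedy semantics the *end* of a span can
  legitimately grow with the sequence (`A(1,2)` on `"A"` vs `"AA"`), so
  span-literal monotonicity would be an incorrect contract.

The scanner is verified against an independent regex-translation oracle
(anchored PCRE matching at every start) on randomly generated patterns, and
the synthetic pattern generator computes its expected matches by a
reachability enumeration over repeat-count vectors — a third route,
independent of both.

## Localization evidence

Two evidence dialects exist. The *consensus* dialect (Arabidopsis) carries a
Bayesian consensus score over many targeting predictors toward chloroplast,
mitochondrion and secretory compartments, plus two experimental-support
flags (proteomics/GFP evidence; a large-scale chloroplast localization
study). The *single-predictor* dialect (rice) carries one predictor's
chloroplast call. The consensus score is an **input**: the aggregation
formula behind it is not public, so recomputing it is out of scope.

The stated decision rule is only "score ≥ 10 is a reliable prediction"
(inclusive, `consensus_supported()`); the sources were otherwise used as
mutual corroboration without an explicit boolean formula. The four-level
lattice used here — `strong` (prediction and experiment), `experimental_only`,
`consensus_only`, `unsupported` — is this package's formalization of that
practice and is labelled as such in reports. For the monotonicity property
the levels are ranked `unsupported < consensus_only < experimental_only <
strong`; experimental evidence outranks prediction-only support, consistent
with low-scoring but MS/MS-supported candidates (e.g. the clathrin heavy
chain candidate, consensus score 0.0) being treated as located. The
mitochondrial and secretory scores are carried for reporting only; the
decisions in the source analysis used only chloroplast support.

## The traffic-light rule

`classify_locus()` colors a candidate **green** iff (a) its annotated role
text matches a vesicle keyword (default `"vesicle transport"`,
`"endocytosis"`; substring, case-insensitive), (b) it is single-subunit, and
(c) its verdict is not `unsupported`. This is the minimal conjunction that
reproduces the published green set exactly: it excludes the coatomer-γ-like
locus At4g34450 (vesicle-role text, but multi-subunit *and* unsupported) and
the Rab GTPase At4g35860 (vesicle-role text but multi-subunit), while
admitting the clathrin heavy- and light-chain candidates. Yellow rationales
record every rule that fired; no priority among them is implied.
`classify_identity()` is red exactly when a subunit has zero candidates.

## Fixtures

The packaged fixtures encode, as the very TSV dialects the CLI consumes, the
published worked example: 29 Arabidopsis chloroplast candidates with domain
sets stated in the source prose and evidence values transcribed digit-for-
digit (22.8, 0.4, 19.9, …), and 15 rice candidates with single-predictor
calls. Query rows whose exact signatures the prose does not state are
marked `inferred = true` and carry the minimal signature consistent with the
reported hits; rows the prose does not determine at all are omitted rather
than guessed. Two fixture-specific notes:

* The source's own summary states 14 rice proteins while its detailed
  enumeration lists 15 distinct loci; the fixture follows the enumeration,
  and the discrepancy is surfaced in `load_fixture("rice")$notes` rather
  than silently reconciled.
* The B-COPI α signature is stated nowhere; it is encoded as
  {PS50082, PS50294, PS00678}, the unique minimal choice that simultaneously
  reproduces the rice locus hitting both α and β′ and the Arabidopsis α
  having no candidate (red).

## The synthetic generator

`generate_screen_instance()` emulates a proteome screen with known ground
truth: planted-single loci carry exactly one signature whose hit closure is
a single identity plus decoy domains; planted-multi loci carry one shared
domain matched as a complete signature by ≥ 2 identities; background loci
carry only decoys. Decoys live in a reserved `PF9xxxx` namespace asserted
disjoint from the catalog, so recovery is exact by construction — a green
recovery test establishes that the screen implements subset matching
correctly, *not* that the screen would behave well on noisy real
annotations (incomplete domain assignments, annotation-version drift and
paralog inflation are outside what the generator emulates; domain *order*
along the sequence is deliberately not modelled because the method is
set-based). Defaults (50 background loci, 8 planted single, 3 planted
multi, decoy pool 40 at rate 0.3, half of loci with supporting evidence)
are of the same order as the real instance the fixtures encode — tens of
candidate loci against a much larger background — and are fixed once here;
every instance is reproducible from its integer seed, and generation never
perturbs the caller's RNG stream.

## Known limitations

* Domain-set matching finds *domain-architecture* similarity only; it
  neither proves homology nor function, which is exactly the epistemic
  status the classification encodes (most candidates are yellow).
* PROSITE profile and Pfam HMM scanning from raw sequence is out of scope;
  those assignments must be provided.
* The evidence lattice is a formalization of prose practice, not a published
  formula; alternative orderings of the two middle levels would not change
  any headline count.
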
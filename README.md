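# coatscreen

Domain-signature screening of chloroplast proteomes for putative homologs of
cytosolic vesicle-coat proteins.

## What it does, and for whom

Plant cells run three cytosolic coated-vesicle systems — COPII, COPI and
clathrin-coated vesicles (CCV, with the AP1–5 adaptor complexes) — all
triggered by small GTPases (Sar1/Arf1). Chloroplasts contain vesicles with
bioinformatic support for a COPII-like machinery; whether COPI- or CCV-like
components also exist there is an open question that can be attacked at desk
scale: reduce each known cytosolic coat subunit to its **domain signature**
(the set of PROSITE/Pfam accessions annotated on one query protein) and ask
which chloroplast-annotated proteins contain such a signature.

`coatscreen` is for plant cell biologists and bioinformaticians who want
that screen — candidate lists, shared-domain ambiguity analysis,
localization-evidence verdicts and a traffic-light summary — as reusable,
tested code rather than a manual database exercise.

The screening rule is set containment. With `D(p)` the domain set of
proteome protein `p` and `S(q)` the signature (full domain set) of query
subunit `q`:

```
p is a candidate for subunit(q)  ⇔  S(q) ⊆ D(p)
```

A locus matching ≥ 2 distinct subunit identities carries "commonly
occurring" domains (e.g. Adaptin N-terminal region PF01602, shared by five
AP large subunits and coatomer γ) and is reported separately. Localization
support combines a consensus targeting score (reliable iff ≥ 10) with two
experimental evidence flags; candidates are annotated, never filtered.

## Worked example

The packaged Arabidopsis fixture encodes the published candidate tables
(domain annotations, role text, evidence scores):

```r
library(coatscreen)
fx  <- load_fixture("arabidopsis")
rep <- run_screen(fx$queries, fx$proteome, fx$evidence)
rep$summary
#> candidate loci: 29 (single-subunit 22, multi-subunit 7; green 2)

count_candidates(rep$result, c("COPI", "B-COPI", "beta-prime"),
                 exclude_multi = TRUE)
#> [1] 8
names(rep$locus_colors)[rep$locus_colors == "green"]
#> [1] "At2g40060" "At3g08530"
classify_identity(c("COPI", "B-COPI", "alpha"), rep$result, rep$locus_colors)
#> <red> COPI/B-COPI/α -- no proteins with the signature domains detected
```

Reading: 29 chloroplast proteins carry some coat-subunit signature, but 7 of
them only via ambiguous shared domains, and only the putative clathrin heavy
chain (At3g08530) and light chain (At2g40060) combine a subunit-specific
signature with a vesicle-transport role and localization support — the
pattern behind the conclusion that a COPI/CCV-like system is unlikely in
chloroplasts. The rice fixture (`load_fixture("rice")`) yields 15 candidate
loci (9 single-subunit, 6 shared-domain).

Greek subunit names accept ASCII aliases (`"beta-prime"` ⇔ `"β′"`,
`"mu2"` ⇔ `"μ2"`).

## Command line

```sh
Rscript inst/exec/coatscreen screen --queries Q.tsv --proteome P.tsv \
    --evidence E.tsv --out outdir/          # candidates.tsv, identities.tsv, report.json
Rscript inst/exec/coatscreen scan --patterns PAT.tsv --fasta SEQ.fa --out annot.tsv
Rscript inst/exec/coatscreen simulate --seed 7 --out sim/
Rscript inst/exec/coatscreen fixtures --name arabidopsis --out fx/
```

`scan` evaluates PROSITE *patterns* (PS0xxxx) against FASTA; profile
(PS5xxxx) and Pfam assignments must be supplied in the proteome table.

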
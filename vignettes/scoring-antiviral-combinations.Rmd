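---
title: "Scoring broad-spectrum antivirals and their combinations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring broad-spectrum antivirals and their combinations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsarank)
```

## The problem

Outbreak response rarely waits for de-novo drug development. Broad-spectrum
antivirals (BSAs) — drugs with demonstrated activity against viruses from two
or more families — are the natural repurposing pool, and two-drug
BSA-containing combinations (BCCs) can add potency, raise the barrier to
resistance, and lower per-drug dosing. The practical question is
prioritization: given hundreds of candidate drugs and a virus of interest
(Voi), which monotherapies and which pairs deserve scarce assay and trial
capacity first?

`bsarank` implements an annotation-driven answer. Everything the scores
consume is an explicit, reviewable table: drug mechanism and target
annotations, virus taxonomy and tropism, and per-pair development status. No
dose-response, synergy-landscape or pharmacokinetic modelling is attempted —
the scores are a transparent triage heuristic over curated knowledge, not an
efficacy prediction.

## The monotherapy score

For a drug against a Voi the package sums six components:

$$\mathrm{BSA\ score} = C_\mathrm{SAR} + C_\mathrm{DDS} + C_\mathrm{TR} +
C_\mathrm{IC} + C_\mathrm{RoA} + C_\mathrm{Phyl} \in [0, 6]$$

* **C_SAR** (structure/identity): 1 if the drug itself has any recorded
  development or testing against the Voi; 0.5 if it has none but is
  structurally similar to a drug that has; 0 otherwise.
* **C_DDS** (development status): how far the drug has progressed *against
  this Voi* — approved/phase 4 → 1, phase 1–3 → 0.75, in vivo → 0.5, in vitro
  → 0.25, untested → 0. The ladder only applies when C_SAR = 1; with C_SAR
  below 1 the drug has no own record to grade, so C_DDS is 0.
* **C_TR** (target relevance): 1 when the drug's confirmed primary target is
  annotated as essential for Voi replication. Essentiality is an explicit
  per-virus annotation (`target_essential_for`), never inferred: "associated
  with replication" has no computable definition, and inference would
  manufacture evidence.
* **C_IC** (immunomodulation): 1 when the drug does not interfere with host
  immunity, 0 when it does. An *unreported* immunomodulatory status scores 1:
  absence of a report is deliberately distinguished from a positive finding.
* **C_RoA** (route suitability): 1 when at least one of the drug's routes of
  administration is suited to at least one organ system the virus infects.
* **C_Phyl** (phylogenetic proximity): the taxonomic relation of the Voi to
  the viruses the drug is known to act on — same genus 1, same family 0.5,
  closely related family 0.25, otherwise 0.

All components are dyadic rationals, so component sums are exact in floating
point and score equality tests can be exact.

Two aggregation choices deserve a note. First, the reference set for C_Phyl
is *every* virus the drug has a non-untested activity record against, and the
maximum relation wins. A drug is typically developed against many viruses;
taking the maximum is the optimistic, order-independent choice and is the only
one consistent with the packaged worked examples (a drug with in-vitro-only
evidence against the Voi itself must still receive C_Phyl = 1). A direct
consequence: C_SAR = 1 forces C_Phyl = 1, because the Voi is then its own
same-genus reference. Second, the structural-similarity tier of C_SAR needs a
similarity provider; without one the 0.5 tier is simply unreachable and the
component degrades to {1, 0}, with a warning rather than an error when a
structure is missing.

## The combination score

For an unordered pair the package multiplies the summed BSA scores by four
coefficients:

$$\mathrm{BCC\ score} = k_\mathrm{DI} \cdot k_\mathrm{DTI} \cdot k_\mathrm{DRS}
\cdot k_\mathrm{RoA} \cdot (\mathrm{BSA}_1 + \mathrm{BSA}_2)$$

* **k_DI** = 0.5 when the mechanism-of-action classes are equal (redundant
  pharmacology), else 1. Equality is string equality after vocabulary
  normalization; out-of-vocabulary classes are preserved as `other:<text>` and
  still compare by equality.
* **k_DTI** = 1.2 / 1.1 / 1.0 for virus–virus / virus–host / host–host
  target-kind pairs (the expected side-effect gradient). An `unknown` target
  kind takes the conservative floor 1.0 and the pair's target class is
  reported as `unknown`. A drug annotated as targeting `both` viral and host
  factors is treated as host-directed here: host involvement is what carries
  the side-effect risk the coefficient grades.
* **k_DRS** = 1.2 when both drugs act on the same named life-cycle stage
  (entry, replication, exit); an `unknown` stage never matches, including
  against another `unknown`.
* **k_RoA** = 0.8 when the drugs share no route (no common administration is
  possible); 1.2 when a shared route is also suited to the Voi's infected
  organ systems; 1.0 for shared-but-unsuited routes.

The attainable multiplier lies in [0.4, 1.728]. A pair is flagged
**effective** when `BCC − (BSA₁ + BSA₂) > 5`, strictly; the margin is exposed
as `effectiveness_delta` in `run_config()` for sensitivity analysis but
defaults to 5. Because the margin is positive, a multiplier ≤ 1 can never
produce an effective pair — one of the invariants the test suite checks by
brute force. Scores are computed, compared and ranked at full precision;
`display_score()` rounds half-away-from-zero only at presentation time, since
published tables mix one- and two-decimal prints (15.8 vs 15.05).

```{r}
b <- ebov_fixture()
compute_bsa_score("merimepodib", "ebov", b)
compute_bcc_score("favipiravir", "merimepodib", "ebov", b)
rank_combinations("ebov", b)[, c("drug_1", "drug_2", "bcc_score", "delta", "effective")]
```

## Tunable parameters

| parameter | default | units / domain | rationale |
| --- | --- | --- | --- |
| `similarity_threshold` | 0.4 | Tanimoto, (0, 1] | conventional ECFP4 similarity floor for "structurally similar"; inclusive (`>=`) |
| `cluster_cutoff` | 0.6 | distance = 1 − Tanimoto | flat-cut level for sub-cluster extraction |
| `effectiveness_delta` | 5 | score points, > 0 | the published promotion margin |
| `route_suitability` | see `default_route_suitability()` | organ system → routes | only a few cells are clinically forced (inhalation ↔ respiratory, intravenous ↔ cardiovascular/systemic); the rest are declared defaults, fully overridable |
| `overrides` | empty | per-entity | manual component/coefficient replacements, always recorded in provenance |

Every rule firing is recorded in the result's `provenance`, including manual
overrides, so a reviewer can reconstruct why a score is what it is.

## Structural analysis

"Structurally similar" is operationalized with hashed circular fingerprints of
radius 2 (diameter 4) over 2048 bits. Structures are parsed from SMILES by
OpenBabel (via ChemmineOB) and desalted by keeping the largest covalent
fragment (most atoms, ties by bond count). Atom environments start from an
(element, heavy-degree, total-bond-order) invariant and are iteratively
refined by hashing the sorted (bond order, neighbor identifier) list, which
makes the fingerprint independent of atom input order: equivalent SMILES
spellings, and the automorphic kekulizations of an aromatic ring, give
identical bit sets. Hydrogen counts and stereochemistry are not part of the
invariant — similarities are therefore not bit-for-bit comparable with other
toolkits' ECFP4 values, only rank-similar; the similarity threshold is exposed
precisely because any such floor is conventional.

Compounds are clustered by average-linkage agglomerative clustering on the
Tanimoto distance with a flat cut at `cluster_cutoff`. Average linkage was
chosen because it is deterministic given the distance matrix and robust to
input order once ties are broken by drug id, which the implementation does by
sorting ids before clustering. Sub-clusters containing **two or more** known
BSAs anchor candidate nomination: every non-BSA member of such a cluster is
proposed, annotated with its maximum similarity to an in-cluster BSA. One BSA
alone never nominates — a singleton anchor is indistinguishable from a chance
neighbor.

## Taxonomy, not trees

Virus relatedness (for C_Phyl and for activity-gap prediction) comes from
user-supplied taxonomy columns — genus, family, and an explicit
`related_families` adjacency — rather than from sequence-derived phylogenies.
Polymerase-based trees cannot even place viruses that do not encode their own
polymerase or reverse transcriptase, whereas a taxonomy table covers every
annotated virus and is exactly reproducible. "Closely related family" has no
formal definition, so it is an explicit, symmetric adjacency the curator
declares (the package honors it in either direction and a family is never
related to itself).

`find_activity_gaps()` inverts the same ladder into predictions: every
(drug, virus) pair with no activity record, where the drug has qualifying
activity against a relative at or above `min_relation`, is reported with the
strongest relation and the implied C_Phyl. Whether in-vitro-only evidence
should count is genuinely unsettled, so the evidence statuses are a filter
argument defaulting to "any non-untested record". Tightening the relation
requirement can only shrink the prediction set — a property the suite tests.

## Packaged fixtures and their editorial choices

`ebov_fixture()` reproduces the published Ebola worked examples from
annotations alone: merimepodib 4.25 = (1, 0.25, 1, 0, 1, 1), favipiravir 5.75
= (1, 0.75, 1, 1, 1, 1), favipiravir–merimepodib 15.84 → "15.8" (effective)
and favipiravir–ribavirin 7.344 → "7.3" (not effective). Two published
numbers require care:

* The prose prints favipiravir's total as 5.57, but its printed components sum
  to 5.75 and the published pair sum of 10 requires 5.75; the fixture treats
  5.57 as a typo and surfaces this in its provenance rather than propagating
  it.
* Ribavirin's own breakdown is never printed — only the pair-sum constraint
  (8.5 − 5.75 = 2.75). Under the component rules, with the pair's published
  coefficients fixing ribavirin as an oral, virus-directed nucleoside analog,
  2.75 admits exactly one decomposition: (0.5, 0, 1, 0, 1, 0.25). The fixture
  realizes it honestly: no direct EBOV record; a *declared* structural
  similarity to favipiravir carried by an explicit-pair similarity provider
  attached to the bundle (both are purine-mimetic nucleoside analogs, but the
  claim is asserted fixture metadata, not a fingerprint computation); approved
  RSV activity with Pneumoviridae annotated as closely related to Filoviridae
  (both order *Mononegavirales*), giving C_Phyl = 0.25; and ribavirin's known
  immunomodulatory activity, giving C_IC = 0. Note that the declared-pair
  provider is attached to the in-memory fixture object; the tabular
  serialization carries annotations only.

`table1_fixture()` extends this to the published reference rows whose printed
scores are reachable from the coefficient rules (didanosine–rilpivirine 20.7,
sofosbuvir–IFN-α 17.4, ribavirin–merimepodib 14.3, favipiravir–merimepodib
15.8), with per-drug activity statuses back-solved to reproduce the published
pair sums; IFN-α additionally carries an intravenous route so the published
multiplier 1.584 arises by rule. Rows whose printed values are arithmetically
unreachable (a foscarnet–favipiravir multiplier of ~1.91 exceeds the 1.728
maximum; one baloxavir–favipiravir row implies k_DTI = 1.1 though both drugs
are virus-directed) are flagged `override_required` and carry no expected
value: they can be reproduced under explicit coefficient overrides, but the
package never guesses the annotations that would fake them.

## The synthetic generator

`generate_bundle(synthetic_spec(...))` produces arbitrary-size bundles for
property testing: viruses spread over `family_count` families (two genera per
family, so every relation tier occurs), a sparse symmetric related-family
adjacency (each ordered family pair related with probability 0.3), drugs
drawing mechanism/target/stage/route annotations from the package
vocabularies, structures drawn from a small list of simple, guaranteed-
parseable SMILES, and activities sampled per pair at `activity_density`
(default 0.15, emulating a sparsely assayed drug–virus matrix). Generation is
a pure function of the spec (seed included) and leaves the caller's RNG state
untouched.

What the generator deliberately does **not** emulate: realistic chemistry
(structures are simple alcohols/aromatics, so structural clusters are
arbitrary), correlated annotations (real nucleoside analogs are almost always
replication-stage, virus-directed), literature-biased activity matrices, or
any dose/potency information. Passing property tests on synthetic bundles
therefore certifies the *arithmetic and invariants* of the scoring rules —
bounds, gating, oracle equivalence, monotonicity — not the epidemiological
validity of the scores on real data.

## Numerical and degenerate-input choices

* Components are dyadic; totals compare exactly. Coefficient products are
  checked to 1e-9 where floating error can enter.
* `display_score()` rounds half away from zero (14.256 → "14.3") and keeps
  trailing zeros ("10.0"); ranking never uses rounded values.
* Ties in `rank_combinations()` break by (score, delta, canonical pair name);
  canonical pairs are lexicographic on normalized ids; identical ids are a
  degenerate-pair error.
* A drug with no routes scores C_RoA = 0 and k_RoA = 0.8, with warnings — the
  conservative reading of "cannot be co-administered".
* Unknown enum values degrade to `unknown` with a warning at load time;
  unknown mechanism classes are preserved as `other:<text>`.
* Empty reference sets (no activity anywhere) give C_Phyl = 0 and make the
  similarity tier of C_SAR unreachable, bounding the no-evidence total at 3.5.

## Problem sizes used by the test suite

The property suites run at deliberately small scale: 200 synthetic bundles of
6 drugs × 4 viruses for the rule-oracle equivalence, 100 random 12-compound
fingerprint sets for the clustering invariants, and 25 bundles for
gap-prediction monotonicity. These sizes already exercise every rule branch
(all component values, all coefficient levels, all relation tiers) while
keeping the default test run in the minutes range; the scoring rules are
per-pair and per-drug, so nothing about them changes at larger n.

## Known limitations

* Scores inherit every bias of the annotations; the package validates
  referential integrity, not curatorial truth.
* The fingerprint is ECFP4-*style*, not toolkit-identical ECFP4; thresholds
  tuned elsewhere do not transfer bit-for-bit.
* Only two-drug combinations are scored; the multiplicative form has no
  published n-drug extension.
* Route suitability is a coarse organ-system map, not pharmacokinetics.
* Published reference rows that contradict the stated coefficient rules stay
  unreproduced by design (`override_required`); reproducing them silently
  would hide the inconsistency.
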
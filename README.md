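# bsarank

Annotation-driven prioritization of broad-spectrum antivirals (BSAs) and
two-drug BSA-containing combinations (BCCs) for pandemic preparedness.

When a poorly characterized virus emerges, the fastest therapeutic option is
repurposing: drugs already active against viruses from several families, alone
or in rational two-drug cocktails. `bsarank` turns curated drug, virus and
drug–virus activity annotations into reproducible priority scores for both
monotherapies and combinations, and supplies the supporting machinery —
structural fingerprint clustering to nominate new BSA candidates, and
taxonomy-based relatedness to flag untested drug–virus pairs worth assaying.

## The scoring system

For a drug against a virus of interest (Voi), the **BSA score** sums six
components:

```
BSA score = C_SAR + C_DDS + C_TR + C_IC + C_RoA + C_Phyl
```

| component | meaning | values |
| --- | --- | --- |
| C_SAR  | drug developed/tested against the Voi (1), structurally similar to such a drug (0.5), else 0 | 1, 0.5, 0 |
| C_DDS  | development status against the Voi: approved/phase 4 → 1, phase 1–3 → 0.75, in vivo → 0.5, in vitro → 0.25; applies only when C_SAR = 1 | 1 … 0 |
| C_TR   | the drug's confirmed primary target is essential for Voi replication | 1, 0 |
| C_IC   | drug does not interfere with the host immune response | 1, 0 |
| C_RoA  | a route of administration suits the infected organ systems | 1, 0 |
| C_Phyl | taxonomic proximity of the Voi to viruses the drug is known to act on: same genus 1, same family 0.5, closely related family 0.25 | 1 … 0 |

For an unordered drug pair, the **BCC score** multiplies the pair's summed BSA
scores by four interaction coefficients:

```
BCC score = k_DI * k_DTI * k_DRS * k_RoA * (BSA score drug1 + BSA score drug2)
```

with `k_DI` = 0.5 for identical mechanisms of action (else 1), `k_DTI` = 1.2 /
1.1 / 1.0 for virus–virus / virus–host / host–host target pairs, `k_DRS` = 1.2
when both drugs hit the same life-cycle stage (else 1), and `k_RoA` = 1.2 /
1.0 / 0.8 for a shared-and-suited / shared / disjoint route of administration.
A combination is flagged **effective** when its BCC score exceeds the pair's
summed BSA scores by strictly more than 5.

## Worked example

```r
library(bsarank)
b <- ebov_fixture()            # favipiravir, merimepodib, ribavirin vs Ebola

compute_bsa_score("merimepodib", "ebov", b)
#> BSA score: merimepodib vs ebov
#>   C_SAR=1 C_DDS=0.25 C_TR=1 C_IC=0 C_RoA=1 C_Phyl=1
#>   total: 4.25

compute_bcc_score("favipiravir", "merimepodib", "ebov", b)
#> BCC score: favipiravir + merimepodib vs ebov
#>   k_DI=1 k_DTI=1.1 k_DRS=1.2 k_RoA=1.2 (virus_host)
#>   BSA sum 10.0 -> BCC 15.8 (delta 5.84) EFFECTIVE

compute_bcc_score("favipiravir", "ribavirin", "ebov", b)
#> BCC score: favipiravir + ribavirin vs ebov
#>   k_DI=0.5 k_DTI=1.2 k_DRS=1.2 k_RoA=1.2 (virus_virus)
#>   BSA sum 8.5 -> BCC 7.3 (delta -1.16) not effective
```

Merimepodib scores 4.25: it has in-vitro anti-EBOV evidence (C_SAR = 1,
C_DDS = 0.25), its host target IMPDH is required for viral RNA synthesis
(C_TR = 1), it suppresses host immunity (C_IC = 0), it is oral against a
multi-organ infection (C_RoA = 1) and was tested on the Voi itself
(C_Phyl = 1). Pairing it with favipiravir multiplies the pair sum of 10 by
1.0·1.1·1.2·1.2 = 1.584, giving 15.84 — more than 5 above 10, so the cocktail
is flagged promising. Favipiravir–ribavirin instead shares a mechanism
(k_DI = 0.5) and lands at 7.3, below its own component sum: a predicted
suboptimal combination.

Ranking, gap prediction and structural nomination:

```r
rank_combinations("ebov", b, effective_only = TRUE)   # 1 row: favipiravir+merimepodib
find_activity_gaps(b, min_relation = "same_family")   # untested taxonomic relatives
fps <- fingerprint_set(c(tam = "...", tor = "...", osp = "..."))  # SMILES
nominate_candidates(cluster_compounds(fps, 0.6), bsa_ids = c("tam", "tor"), fps)
```

A thin command-line front end ships in `inst/cli/bsarank`
(`validate`, `score-bsa`, `score-bcc`, `rank`, `gaps`, `overlap`,
`sar-cluster`, `simulate`, `fixtures`).

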
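# richconn

Rich-club analysis of weighted structural brain connectomes in R.

## What it is for

Case–control diffusion-tractography studies commonly ask whether a
disorder preferentially weakens the *rich club* — the high-degree hub
regions of the structural network and the strong white-matter connections
among them. `richconn` implements that analysis as a tested, fully seeded
pipeline for researchers working with connectivity matrices (it starts
from streamline-count/FA/volume ingredients, not from raw images):

* per-subject weighted networks, `w_ij = FN_ij · FA_ij / ((v_i + v_j)/2)`,
  with streamline-count thresholds (FN ≥ 1, 2, 3, 5, 10);
* group-consensus backbones (edges present in ≥ 50/75/90% of subjects);
* global and nodal graph metrics (Cp, Lp, Eg, Eloc, nodal efficiency),
  small-world indices γ, λ, σ against Maslov–Sneppen degree-preserving
  null networks, and metric-versus-sparsity AUCs (sparsity 0.10–0.40);
* the weighted rich-club coefficient
  `Φʷ(k) = W_{>k} / Σ_{l≤E_{>k}} w_l^{ranked}`
  normalized by its mean over rewired nulls (`Φ_norm(k) > 1` across a k
  interval indicates rich-club organization), rich-node selection by
  top-N degree or by degree > k, and rich/feeder/local edge classes;
* permutation group tests in the Freedman–Lane scheme (covariates
  residualized once, labels permuted; add-one two-tailed p), Holm (FWE)
  and Benjamini–Hochberg (FDR) corrections, covariate-adjusted Spearman
  correlations, Mann–Whitney U and 2×2 χ²;
* a synthetic-cohort generator that plants hub organization, a patient
  deficit concentrated on hub connections, and clinical-score couplings —
  so the whole pipeline is testable end to end with no data download;
* plain-text I/O (matrix TSV, atlas/phenotype CSV) and BrainNet Viewer
  `.node`/`.edge` exports.

## Worked example

```r
library(richconn)

cfg <- simulationConfig(seed = 7)       # 43 patients / 42 controls, 90 nodes
co  <- generateCohort(cfg)
co
#> Cohort: 85 subjects (control=42, patient=43), 90 nodes, seed 7

nets  <- lapply(connectomes(co), buildNetwork, fnThreshold = 1)
isPat <- phenotypes(co)$group == "patient"

bbC <- groupConsensus(nets[!isPat], prevalence = 0.75)
bbC
#> ConsensusBackbone: 90 nodes, 825 edges, density 0.206
#>   consensus of 42 subjects at prevalence >= 0.75

richC <- identifyRichNodes(bbC, topN = 32)
normalizedRichClub(bbC, nNull = 100, seed = 11)
#> RichClubCurve: k in [1, 35], 100 nulls; phi_norm > 1 at 30/33 k

sP <- subjectClassStrengths(nets[isPat],
        identifyRichNodes(groupConsensus(nets[isPat], 0.75), topN = 32))
sC <- subjectClassStrengths(nets[!isPat], richC)
phe  <- phenotypes(co)
covs <- rbind(
  data.frame(age = phe$age, sex = ifelse(phe$sex == "male", 1, 0),
             education = phe$education)[isPat, ],
  data.frame(age = phe$age, sex = ifelse(phe$sex == "male", 1, 0),
             education = phe$education)[!isPat, ])

permutationGroupTest(sP$rich, sC$rich, covs, nPerm = 5000, seed = 13)
#> Permutation test: observed diff -0.8542, 5000 permutations, p = 0.0002

spearmanPartial(phe$ISI[isPat], sP$rich, covs[seq_len(sum(isPat)), ])
#> Spearman (partial on age,sex,education): rho = 0.420, p = 0.00507, n = 43
```

The planted 30% hub-connection deficit is detected (patients' rich-club
strength sits far below controls after removing age, sex and education),
the control backbone shows rich-club organization (`Φ_norm > 1` over a
contiguous degree range), and the planted insomnia-severity coupling with
rich-club strength is recovered within the patient group.

`runPipeline(runConfig(...), outDir = "out/")` runs every stage over the
full FN-threshold × prevalence grid and writes `report.json`, CSV tables
and BrainNet Viewer exports; `inst/scripts/richconn-pipeline.R` is a thin
shell front-end over the same functions.

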
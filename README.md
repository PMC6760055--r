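# ntsqbd

Quality-by-design (QbD) analysis tools for the manufacture of notoginseng
total saponins (NTS) — the saponin-enriched *Panax notoginseng* extract
behind the Xuesaitong injection — covering the chain from raw-material
characterization to a release decision for incoming material lots.

The package is built around four ideas:

1. **Quality attributes.** A material lot is characterized by what the
   standardized 80% ethanol reflux extraction can actually recover from it:
   extractable contents of notoginsenoside R1 and ginsenosides Rg1, Re,
   Rb1, Rd (`Z1..Z5`, mg/g) plus extractable dry matter (`Z6`, mg/g). A
   manufacturing run's eluate is summarized by the five saponin purities,
   the total saponin purity (TSP), the dry-matter yield (DMY) and total
   saponin yield (TSY = TSP × DMY).
2. **Screening regression.** Over a 32-run, 10-factor definitive screening
   design executed on 16 different material lots, each process critical
   quality attribute (CQA) — ginsenoside Rd purity and total saponin
   purity — is modeled as

   `Y = a0 + Σ b_i X_i + Σ c_k Z_k`

   with uncoded process parameters `X` and raw material attributes `Z`.
   Bidirectional stepwise selection at α = 0.05 retains the critical
   process parameters (CPPs) and critical material attributes (CMAs);
   squares and interactions of the CPPs are then offered and (on this
   dataset) all rejected.
3. **Probability-based design space.** Measurement error (multiplicative
   Gaussian, relative SD 0.04) is propagated by Monte Carlo: responses are
   perturbed, models refitted, and every grid point of the CPP box scored
   by the probability that both CQA limits (Rd purity ≥ 3.5%, TSP ≥ 85%)
   are met. The design space is the region with probability ≥ 0.90.
4. **Material grading.** Each CQA model plus its limit yields a linear
   acceptance inequality over `X` and `Z`. With process parameters free in
   their investigated ranges, a lot is *acceptable* iff the system is
   feasible (decided exactly); with parameters fixed, the inequalities
   collapse to conditions on `Z` alone that split lots into *high* and
   *low* quality.

## Worked example

```r
library(ntsqbd)
study <- nts_study()              # bundled 32-run screening study

# screen both CQAs
m1 <- stepwise_fit(study$data, "rd_purity",
                   c(paste0("X", 1:10), paste0("Z", 1:6)))
m1$terms
#> [1] "X1"  "X9"  "X10" "Z5"  "Z6"
m1$stats$r.squared
#> [1] 0.9348701

m2 <- stepwise_fit(study$data, "total_saponin_purity",
                   c(paste0("X", 1:10), paste0("Z", 1:6)))
identify_critical(list(m1, m2))
#> $cpps
#> [1] "X1"  "X9"  "X10"
#> $cmas
#> [1] "Z1" "Z2" "Z4" "Z5" "Z6"

# predict the verification point for lot PN20
predict(study$published_models$rd_purity,
        data.frame(X1 = 90, X9 = 60, X10 = 120, Z5 = 6.43, Z6 = 227)) * 100
#> [1] 4.830164

# grade the four example lots under the fixed manufacturing process
iq   <- derive_inequalities(study$published_models, nts_cqa_limits())
simp <- simplify_fixed(iq, nts_fixed_process())
sapply(seq_len(4), function(i)
  classify_fixed(simp, study$grading_examples[i, ])$verdict)
#> [1] "low"  "high" "low"  "high"
```

The retained terms say that extraction ethanol concentration (`X1`),
elution ethanol concentration (`X9`) and elution time (`X10`) are the
process levers for Rd purity, while a lot's extractable Rd (`Z5`) helps
and its total extractable dry matter (`Z6`) dilutes it. The grading
verdicts reproduce the study's released/withheld decisions for lots
PN17–PN20.

A full run — screening, design space for a chosen lot, grading, result
files — is `run_qbd_pipeline("results/", design_space_for = "PN18")`.
Synthetic datasets with the same statistical structure come from
`generate_dataset(generator_spec(), seed = 1)`.

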
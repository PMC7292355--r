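# dialyzr

Dosing drugs in hemodialysis (HD) patients requires knowing how much of a
dose the dialysis session removes, but clinical dialyzability data are
sparse and inconsistent, and single-timepoint dialyzer clearances miss
whole-body effects such as the post-dialysis rebound of vancomycin.
`dialyzr` implements an analysis pipeline for a miniaturized **rat
hemodialysis model**: it quantifies drug removal by dialysate recovery in
anephric rats dialyzed on a down-scaled dialyzer, and extrapolates the
result to patients using the species differences in plasma protein binding
(PBR) and volume of distribution (Vd).

The package is aimed at pharmacokineticists and dialysis researchers who
want to analyse small-animal dialysis experiments or explore the
rat-to-human prediction equations.

## What it computes

**Dialysis adequacy.** Dialyzer clearance from an arteriovenous pair with
hematocrit correction,

> CL = (Ca − Cv)/Ca · Q_B · (1 − Hct),

and the second-generation Daugirdas single-pool Kt/V,

> Kt/V = −ln(R − 0.008·Td) + (4 − 3.5·R)·UFV/BW,  R = BUN_post/BUN_pre.

**Drug removal.** The dialysate-recovery removal rate
100 · C_dialysate · V_dialysate / dose, and its first-order extrapolation to
another session length, 100·(1 − (1 − R/100)^(t'/t)) — canonically from the
rat's 2-h session to the clinical 4-h session.

**Protein binding and distribution.** PBR = 100·(C_T − C_F)/C_T from
ultrafiltration, and steady-state Vd by noncompartmental moment analysis
(linear trapezoid + log-linear tail; V_ss = D·AUMC/AUC² − D·T_inf/(2·AUC)).

**Cross-species prediction.** Four candidate ordinary-least-squares models
of human dialyzability DD_human from the rat 4-h removal rate x, fitted on
six drugs (amikacin, aprindine, vancomycin, doripenem, valproate,
acetaminophen) and ranked by adjusted R²:

1. DD_human = a0 + a1·x
2. DD_human = a0 + a1·x·(100 − PBR_human)/(100 − PBR_rat)
3. DD_human = a0 + a1·x + a2·Vd_human/Vd_rat
4. DD_human = a0 + a1·x + a2·[(100 − PBR)/Vd]_human / [(100 − PBR)/Vd]_rat

**Synthetic studies.** A two-compartment PK simulator with a constant-rate
infusion and an intermittent dialyzer clearance acting on the unbound
central concentration generates whole studies (plasma curves, cumulative
dialysate mass, the rebound) for end-to-end testing.

## Worked example

```r
library(dialyzr)

# 2-h vancomycin removal in the rat, carried to a 4-h session
extrapolate_removal(17.8, t_measured = 2, t_target = 4)
#> [1] 32.4316

# dialysis dose of a rat session: BUN 117 -> 106 mg/dL in 2 h,
# 2.4 g fluid removed, 658.4 g post-dialysis weight
ktv_daugirdas(dialysis_session(117, 106, 2, 2.4, 658.4, "mL_g"))
#> [1] 0.1195751

# fit the four prediction equations on the packaged six-drug table
res <- run_fit()
res$table
#>   equation        a0       a1         a2        r2    adj_r2           p
#> 1        1 1.4825345 1.263039         NA 0.8494808 0.8118510 0.008962444
#> 2        2 0.9773273 1.225410         NA 0.9481946 0.9352433 0.001024327
#> 3        3 1.2947148 1.261981  0.3497134 0.8495350 0.7492251 0.058365071
#> 4        4 3.3327743 1.217579 -0.1799305 0.8509044 0.7515073 0.057570155
res$selected
#> [1] 2
```

Equation 2 — rat removal scaled by the human/rat unbound-fraction ratio —
has the highest adjusted R² (0.935) and is selected: adjusting the rat
measurement for the species difference in protein binding markedly improves
the prediction (doripenem is the drug it rescues, being far more
protein-bound in rat than in human). Predicted human dialyzability for a
drug is then `predict_dd_human(res$fits$eq2, record)`.

A thin command-line wrapper over the same functions ships in
`inst/cli/dialyzr.R` (`metrics`, `fit`, `reproduce` subcommands).

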
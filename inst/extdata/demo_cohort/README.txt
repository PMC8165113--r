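Synthetic demo cohort (generated by valvesex::simulate_clinical /
simulate_expression with seed 2024; no patient data). 5 + 5 patients,
three tissue samples each, 150 genes with planted sex, calcification and
sex-by-calcification structure. Regenerate with:
  Rscript inst/cli/valvesex.R simulate --out inst/extdata/demo_cohort --seed 2024
(expression values rounded to 4 decimals for compactness).
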
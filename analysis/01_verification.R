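#!/usr/bin/env Rscript
# Verification battery: every analytic-oracle check at the quick tier.
# Writes results/verification.csv and prints a pass/fail table.

library(stenoflow)

dir.create("results", showWarnings = FALSE)
rep <- validate_suite("quick")
write.csv(rep, "results/verification.csv", row.names = FALSE)
print(rep, row.names = FALSE)
if (all(rep$pass)) {
  cat("\nAll oracle checks pass: the discretization reproduces",
      "Hagen-Poiseuille, the shear-thinning quadrature oracle, Couette",
      "dissipation heating, exact mass conservation and a monotone",
      "grid-refinement trend.\n")
} else {
  cat("\nSome checks FAILED - see results/verification.csv\n")
}
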
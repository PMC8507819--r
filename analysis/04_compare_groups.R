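#!/usr/bin/env Rscript
# Step 4 — nonparametric comparison design.
#
# Within each occupation, the four workplace concepts are compared on the
# per-subject rel. av. RST with a Friedman test, Conover-Iman pairwise
# contrasts and Bonferroni-Holm correction (family: the 6 contrasts of one
# outcome). Between occupations, Mann-Whitney U tests per concept and
# outcome on both the rel. av. RST and the median score (family: the 9
# outcomes within one concept and measure). Alpha 0.05 throughout.
#
# Inputs:  results/subject_summaries.csv
# Outputs: results/dwc_comparisons.csv, results/occupation_comparisons.csv

suppressPackageStartupMessages(library(rulatime))

ss <- read.csv("results/subject_summaries.csv")

dwc_cmp <- rbind(compare_dwcs(ss, "D"), compare_dwcs(ss, "DA"))
occ_cmp <- compare_occupations(ss)
write.csv(dwc_cmp, "results/dwc_comparisons.csv", row.names = FALSE)
write.csv(occ_cmp, "results/occupation_comparisons.csv", row.names = FALSE)

sig <- dwc_cmp[dwc_cmp$favored != "none", ]
cat("Concept contrasts passing the Friedman gate and Holm-adjusted alpha = 0.05:\n")
if (nrow(sig)) {
  print(sig[, c("occupation", "outcome", "contrast", "statistic", "p_adj",
                "favored", "stars")], row.names = FALSE)
} else cat("  none\n")

sig_occ <- occ_cmp[occ_cmp$favored != "none", ]
cat("\nOccupation contrasts (Mann-Whitney U, Holm within concept):\n")
if (nrow(sig_occ)) {
  print(sig_occ[, c("dwc", "outcome", "measure", "U", "p_adj", "favored",
                    "stars")], row.names = FALSE)
} else cat("  none\n")

cat("\nReading: with the default design, the dentists' concept-4 neck relief",
    "is the designed (and recovered) signal; anything else that appears is",
    "expected to be sporadic at the 5% level.\n")
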
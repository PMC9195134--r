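#!/usr/bin/env Rscript
# Step 3: apply the three-tier delineation rule (MLSA 0.008 / 0.014 tiers,
# dDDH 70% / ANIm 96.7% cuts, borderline bands deferring to polyphasic
# evidence) to every packaged pair.

suppressPackageStartupMessages(library(strepdelim))
dir.create("results", showWarnings = FALSE)

tbl <- streptomyces_pairs()
res <- classify_table(tbl)
print(res)

write.table(res$verdicts, "results/verdicts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(verdict_report(res, format = "json"), "results/verdicts.json")

border <- res$verdicts[res$verdicts$state == "BORDERLINE_POLYPHASIC", ]
cat("\nPairs deferred to polyphasic evidence (just below a cut-off):\n")
print(border[, c("species_a", "species_b")], row.names = FALSE)

# The four pairs whose junior names were reduced to heterotypic synonyms;
# the rule must call each conspecific on genome metrics.
emended <- list(
  c("S. antimycoticus NBRC 12839T", "S. melanosporofaciens DSM 40318T"),
  c("S. filipinensis JCM 4369T", "S. durhamensis NRRL B-3309T"),
  c("S. recifensis NRRL B-3811T", "S. griseoluteus JCM 4765T"),
  c("S. olivaceoviridis JCM 4499T", "S. corchorusii DSM 40340T"))
cat("\nEmendation worked examples:\n")
for (pair in emended) {
  i <- which((res$verdicts$species_a == pair[1] &
                res$verdicts$species_b == pair[2]) |
               (res$verdicts$species_a == pair[2] &
                  res$verdicts$species_b == pair[1]))
  cat(sprintf("  %s / %s -> %s\n", pair[1], pair[2],
              res$verdicts$state[i]))
}
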
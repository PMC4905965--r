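#!/usr/bin/env Rscript
# Stage 5: cohort trends in connectivity strength.
#
# Correlates each reference edge's per-cohort lagged-path coefficient
# with cohort index, classifies rising/falling trends at alpha = 0.05
# (two-sided, G - 2 df), pairs significant edges by receiving node, and
# repeats the trend fit split by sex.  Writes the trend table, the
# pairing report and the sex-split comparison.

library(usemnet)
library(jsonlite)

panel <- read_panel("results/panel/manifest.json")
covs <- prepare_panel(panel, censor = TRUE)$covs
ref <- dmn_reference_model()
m13 <- build_usem(ref$nodes$name, ref$edges[, c("source", "target")])

fit <- fit_ml(m13, covs, ci = FALSE)
tr <- decade_trends(fit)
write.table(tr, "results/trends.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

pairing <- pair_by_receiver(tr)
write_json(pairing, "results/receiver_pairing.json", auto_unbox = TRUE,
           pretty = TRUE)

sx <- sex_split_trends(panel, m13)
write.table(sx$F, "results/trends_female.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(sx$M, "results/trends_male.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sum(tr$class == "rising"), "rising and", sum(tr$class == "falling"),
    "falling significant trends of", nrow(tr), "edges\n")
cat("paired receivers:", paste(pairing$paired, collapse = ", "), "\n")
cat("divergent edges between sexes:", nrow(sx$divergent), "\n")
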
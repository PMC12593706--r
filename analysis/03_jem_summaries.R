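#!/usr/bin/env Rscript
# Summaries of the assembled JEM: the four-digit aggregated view, the
# highest- and lowest-exposed jobs per exposure, exposure fold ratios,
# and the uniform trimester shift of the standing matrix.

library(opajem)

jem <- read.csv("results/jem.csv", colClasses = c(code = "character"))
class(jem) <- c("jem_table", "data.frame")
attr(jem, "reference_age") <- NA_real_

l4 <- jem_level4(jem)
write.csv(as.data.frame(l4), "results/jem_level4.csv", row.names = FALSE)

for (e in unique(jem$exposure)) {
  ex <- jem_extremes(jem, e, k = 3)
  cat(sprintf("== %s: three highest / lowest exposed codes (hours per 8-h day) ==\n", e))
  print(cbind(rank = 1:3, top = ex$top, bottom = ex$bottom), row.names = FALSE)
  cat(sprintf("fold ratio (max/min): %.1f\n\n", fold_ratio(jem, e)))
}

st <- jem[jem$exposure == "standing", ]
shift <- tapply(st$hours_per_8h, st$trimester, mean)
cat(sprintf("standing NP -> T3 mean shift: %.2f hours (uniform across codes)\n",
            shift[["NP"]] - shift[["T3"]]))
prov <- table(st$provenance[st$trimester == "NP"])
cat(sprintf("provenance: %d measured (BLUP-adjusted), %d expert-only codes\n",
            prov[["measured"]], prov[["expert_only"]]))
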
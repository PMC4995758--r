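#!/usr/bin/env Rscript
# Deregressed breeding values: fit the repeated-measurement mixed model
# y = alpha + block + plate + g + e by REML, extract EBVs (BLUPs) and
# their prediction error variances, and deregress by the reliability
# r2 = 1 - PEV / sigma2_g so the response used in association is free
# of BLUP shrinkage.

library(thetaGWAS)
library(data.table)

dir <- "results/study"
records <- as.data.frame(fread(file.path(dir, "phenotypes.csv")))
records$block <- factor(records$block)
records$plate <- factor(records$plate)

fit <- fit_mixed_model(records)
print(fit)
debv <- deregress(fit)

fwrite(debv, file.path(dir, "debv.tsv"), sep = "\t")
fwrite(data.table(parameter = c("sigma2_g", "sigma2_e",
                                names(fit$fixed)),
                  estimate = c(fit$sigma2_g, fit$sigma2_e, fit$fixed)),
       file.path(dir, "fit_summary.tsv"), sep = "\t")

cat(sprintf("Repeatability (per record): %.3f\n",
            fit$sigma2_g / (fit$sigma2_g + fit$sigma2_e)))
cat(sprintf("Reliability range: %.3f - %.3f; DEBV sd: %.2f\n",
            min(debv$r2), max(debv$r2), sd(debv$debv)))
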
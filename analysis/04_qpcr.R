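#!/usr/bin/env Rscript
# qPCR enrichment arithmetic on the simulated Ct table: per-target fold
# changes by 2^-ddCt against the reference gene and control condition, the
# percent-input and reference-region conventions on a worked ChIP example,
# and replicate summaries with an unpaired t test.
# Run analysis/01_simulate.R first.

suppressMessages(library(majsat))

sim <- "results/simulated"
ct <- read.csv(file.path(sim, "ct_table.csv"))
truth <- read.csv(file.path(sim, "ct_truth.csv"))

folds <- expression_folds(ct)
folds$true_fold <- truth$true_fold[match(folds$target, truth$target)]
write.csv(folds, "results/qpcr_folds.csv", row.names = FALSE)
cat("recovered folds (Ct noise sd 0.15):\n")
print(folds)

## worked ChIP example: percent input and reference-region normalization ----
# an IP 3 cycles above a 10% input is 80% of input
chip <- data.frame(region = c("majsat1", "intergenic"),
                   ct_ip = c(25, 29), ct_input = c(28, 29))
chip$percent_input <- percent_input(chip$ct_ip, chip$ct_input, 0.10)
chip$over_intergenic <- relative_to_reference(
  chip$percent_input, chip$percent_input[chip$region == "intergenic"])
write.csv(chip, "results/chip_enrichment.csv", row.names = FALSE)
print(chip)

## replicate summary with an unpaired t test --------------------------------
reps <- do.call(rbind, lapply(1:3, function(r) {
  g <- gen_ct_table(truth[truth$target == "majsat1", c(1, 2)] |>
                      transform(name = target, ct_reference = 24),
                    noise_sd = 0.15, rng_seed = 100 + r)
  data.frame(condition = "KO", value = expression_folds(g$ct)$fold)
}))
set.seed(42)
wt <- data.frame(condition = "WT", value = 1 + rnorm(3, 0, 0.05))
s <- summarize_replicates(rbind(reps, wt))
cat(sprintf("\nKO vs WT fold: %.2f vs %.2f, t = %.2f, p = %.4f\n",
            s$summary$mean[1], s$summary$mean[2], s$t, s$p))
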
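#!/usr/bin/env Rscript
# Generates every synthetic input the downstream analyses consume, with its
# ground truth: a major-satellite-like tandem array carrying planted miR-30
# family seed sites, RepeatMasker annotation files in both dialects, a
# RIP/input small-RNA count table with a planted AGO-loaded subset, qPCR Ct
# tables with known fold changes, and one two-channel nuclear scene.
# Everything lands under results/simulated/.

suppressMessages(library(majsat))

out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260924L

## miR-30-3p-like guide and its 8mer site -----------------------------------
mirnas <- data.frame(
  mirna_id = c("miR-30a-3p", "miR-30d-3p", "miR-30e-3p",
               "miR-139-5p", "miR-6989-3p"),
  mature_sequence = c(
    # same seed (positions 1-8) for the three miR-30-3p family members
    "CUUUCAGUCGGAUGUUUGCAGC",
    "CUUUCAGUCGGAUGUUUACAGC",
    "CUUUCAGUCAGAUGUUUACAGC",
    "UCUACAGUGCACGUGUCUCCAGU",
    "UCUGCUUGGGAGACAGGCUGGG"))
writeLines(paste0(">", mirnas$mirna_id, "\n", mirnas$mature_sequence),
           file.path(out, "mirnas.fa"))
motif30 <- seed_motif("miR-30a-3p", mirnas$mature_sequence[1])$motif
cat("miR-30-3p family 8mer site:", motif30, "\n")

## tandem array: 234 bp x 100 units, one planted site per unit --------------
sp <- tandem_repeat_spec(unit_length = 234, n_units = 100,
                         planted_sites = data.frame(
                           motif = motif30, offset_in_unit = 117,
                           every_k_units = 1),
                         rng_seed = seed)
tr <- gen_tandem_repeat(sp)
writeLines(c(">sat_chrX", tr$sequence), file.path(out, "satellite.fa"))
write.csv(tr$truth, file.path(out, "satellite_truth.csv"), row.names = FALSE)
cat("tandem array:", nchar(tr$sequence), "bp,", nrow(tr$truth),
    "planted sites\n")

## RepeatMasker annotations straddling the 20 kb rule -----------------------
regs <- data.frame(
  chrom = c("sat_chrX", "chr9", "chr9", "JH584304.1", "GL456383.1"),
  start = c(0L, 1000L, 19000L, 5000L, 0L),
  end = c(23400L, 18900L, 40000L, 24999L, 500L),
  repeat_name = c("GSAT_MM", "GSAT_MM", "GSAT_MM", "GSAT_MM", "SYNREP_MM"),
  strand = c("+", "+", "+", "-", "+"))
gen_repeatmasker_file(regs, file.path(out, "rmsk.out"), "out")
gen_repeatmasker_file(regs, file.path(out, "rmsk_ucsc.tsv"), "ucsc_table")

## RIP vs input count table: 50 AGO-loaded of 500 ---------------------------
cts <- count_table_spec(n_mirnas = 500,
                        enriched_ids = sprintf("miR-%04d", 26:75),
                        effect_log2fc = 2, dispersion = 0.05,
                        rng_seed = seed)
ctab <- gen_count_table(cts)
write.table(cbind(mirna_id = rownames(ctab$counts), ctab$counts),
            file.path(out, "rip_counts.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
write.csv(ctab$truth, file.path(out, "rip_truth.csv"), row.names = FALSE)
cat("count table:", nrow(ctab$counts), "miRNAs,",
    sum(ctab$truth$class == "enriched"), "planted enriched\n")

## qPCR Ct tables with known folds ------------------------------------------
targets <- data.frame(name = c("majsat1", "majsat2", "Dazl", "MusD"),
                      true_fold = c(4, 0.5, 2.5, 1),
                      ct_reference = c(24, 26, 22, 28))
g <- gen_ct_table(targets, noise_sd = 0.15, rng_seed = seed)
write.csv(g$ct, file.path(out, "ct_table.csv"), row.names = FALSE)
write.csv(g$truth, file.path(out, "ct_truth.csv"), row.names = FALSE)

## one imaging scene ---------------------------------------------------------
sc <- gen_nuclear_images(image_scene_spec(rng_seed = seed))
paths <- write_scene(sc, out, "scene")
cat("scene:", nrow(sc$truth$nuclei), "nuclei,",
    nrow(sc$truth$foci), "marker foci (",
    sum(sc$truth$foci$colocalized), "colocalized )\n")
cat("simulated inputs written to", out, "\n")
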
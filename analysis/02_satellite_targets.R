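#!/usr/bin/env Rscript
# Major-satellite region selection and miRNA seed-site ranking.
# Parses the simulated RepeatMasker annotations (both dialects must agree),
# keeps GSAT_MM hits, selects regions of >= 20 kb, attaches sequences, scans
# each miRNA's 8mer site across regions and strands, and ranks the miRNAs.
# Run analysis/01_simulate.R first.

suppressMessages(library(majsat))

sim <- "results/simulated"
out <- "results"

ann_out <- parse_annotations(file.path(sim, "rmsk.out"), "out")
ann_ucsc <- parse_annotations(file.path(sim, "rmsk_ucsc.tsv"), "ucsc_table")
stopifnot(identical(ann_out[c("chrom", "start", "end", "strand")],
                    ann_ucsc[c("chrom", "start", "end", "strand")]))

sat <- filter_by_name(ann_out, "GSAT_MM")
cat("annotations:", nrow(ann_out), "->", nrow(sat), "GSAT_MM\n")

regions <- select_regions(sat, min_length = 20000, merge_gap = 0)
cat("regions >= 20 kb:", nrow(regions), "\n")
print(regions[c("region_id", "length")])

# only the simulated satellite contig has a FASTA; scan that one
regions <- regions[regions$chrom == "sat_chrX", ]
regions <- attach_sequences(regions, file.path(sim, "satellite.fa"))

mirnas <- read_mirnas(file.path(sim, "mirnas.fa"))
tab <- scan_regions(mirnas, regions, site_type = "8mer",
                    strand_mode = "both")
write.table(tab, file.path(out, "site_counts.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

ranking <- rank_mirnas(tab, top_n = 5)
write.table(ranking, file.path(out, "mirna_ranking.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("\ntop miRNAs by 8mer site count (both strands):\n")
print(ranking)

truth <- read.csv(file.path(sim, "satellite_truth.csv"))
cat("\nplanted sites:", nrow(truth),
    "| top family plus-strand count:",
    tab$count[tab$mirna_id == "miR-30a-3p" & tab$strand == "+"], "\n")
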
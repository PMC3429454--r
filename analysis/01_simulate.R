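#!/usr/bin/env Rscript
# Stage 1: simulate the study.
#
# Generates the synthetic two-arm intervention lipidome under the default
# design: 16 fish-oil (FO) and 17 sunflower-oil (HOSO) subjects sampled at
# weeks 0/3/7; 260 identified species across 11 lipid classes; 28% of the
# species in each class respond in the FO arm at the published effect scale,
# with class totals held constant (within-class remodeling). Raw intensities
# are written together with the internal-standard table and the ground-truth
# labels that later stages are scored against.

suppressMessages(library(lipidblocks))

seed <- 1L
out <- "results/synthetic"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

design <- study_design(seed = seed)
print(design)
sim <- generate_study(design)
print(sim$dataset)

write_dataset_tsv(sim$dataset, file.path(out, "raw_intensities.tsv"),
                  meta = c(paste("seed:", seed), "unit: intensity"))
write_standards_tsv(sim$standards, file.path(out, "standards.tsv"),
                    meta = paste("seed:", seed))
ann <- sim$dataset$species[c("peak_id", "raw_name", "identified")]
utils::write.table(ann, file.path(out, "annotations.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(sim$truth, file.path(out, "ground_truth.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("\n%d of %d species are planted responders (|log2FC| %.2f-%.2f)\n",
            sum(sim$truth$is_responder), nrow(sim$truth),
            min(abs(sim$truth$true_log2fc[sim$truth$is_responder])),
            max(abs(sim$truth$true_log2fc[sim$truth$is_responder]))))
cat("wrote", out, "\n")
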
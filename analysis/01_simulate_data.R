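#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs every later stage consumes.
#
# The generator emulates the statistical structure of the real data sources:
# two proteomic pQTL platforms (strong cis instruments, F around 100, at the
# 35k-participant scale), a small binary outcome GWAS (1917 cases / 9292
# controls worth of information), and a 50-vs-50 extracellular-vesicle
# proteomics cohort. Four of twenty proteins carry a true causal effect on
# the outcome.

library(scadmr)

seed <- 20260924L
out_dir <- "results/data"
dir.create(file.path(out_dir, "ld"), showWarnings = FALSE, recursive = TRUE)
write_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

message("Simulating 20-protein, 2-platform scan inputs (seed ", seed, ") ...")
study <- simulate_scan_study(n_traits = 20, k_instruments = 3, n_causal = 4,
                             seed = seed)
for (pl in names(study$exposures)) {
  combined <- do.call(rbind, c(lapply(names(study$exposures[[pl]]), function(tr) {
    cbind(trait_id = tr, as.data.frame(study$exposures[[pl]][[tr]]))
  }), make.row.names = FALSE))
  write_tsv(combined, file.path(out_dir, paste0("exposure_", pl, ".tsv")))
}
write_tsv(as.data.frame(study$outcome), file.path(out_dir, "outcome_gwas.tsv"))
write_tsv(study$loci, file.path(out_dir, "loci.tsv"))
write_tsv(data.frame(trait_id = names(study$truth$beta_true),
                     beta_true = study$truth$beta_true),
          file.path(out_dir, "truth_scan.tsv"))
# per-locus regional LD as square TSVs with a variant-id header column
for (gene in names(study$ld)) {
  ld <- study$ld[[gene]]
  write_tsv(data.frame(variant_id = rownames(ld), ld, check.names = FALSE),
            file.path(out_dir, "ld", paste0(gene, ".tsv")))
}

message("Simulating the 50/50 validation proteomics cohort ...")
prot <- simulate_proteomics(n_case = 50, n_control = 50, n_proteins = 20,
                            effect_map = c(ECM1 = 0.633),
                            missing_proteins = c("SPON1", "AFAP1", "STAT6"),
                            sigma = 1, seed = seed + 1L)
write_tsv(data.frame(protein_id = rownames(prot$intensities),
                     prot$intensities, check.names = FALSE),
          file.path(out_dir, "validation_intensities.tsv"))

# clinical covariates matching the validation cohort's recoverable counts:
# diabetes 2/50 vs 0/50, hypertension 13/50 vs 1/50, age ~41 vs ~44 years
set.seed(seed + 2L)
clinical <- data.frame(
  group = prot$groups,
  age = c(rnorm(50, 41.2, 9.2), rnorm(50, 44.0, 8.6)),
  diabetes = c(rep("yes", 2), rep("no", 48), rep("no", 50)),
  hypertension = c(rep("yes", 13), rep("no", 37), rep("yes", 1), rep("no", 49)))
write_tsv(clinical, file.path(out_dir, "validation_clinical.tsv"))

message("Wrote synthetic inputs under ", out_dir)
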
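#!/usr/bin/env Rscript
# Build the demo cohort the downstream analyses run on: 10 control + 9 case
# donors, 24 subtypes in the four-level hierarchy, with planted condition
# effects in one principal and one interneuron subtype, a depleted
# interneuron subtype, and three co-expression modules (one condition-
# coupled) inside the L2_Cux2 family. Writes the cohort (MTX + TSV), the
# gene-set collection (GMT), curated/autopsy gene lists, the smFISH
# intensity table, and the planted truth for later comparison.

suppressMessages(library(episcope))
seed <- 20240917L
out <- "results/cohort"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- cohort_config(
  n_control_samples = 10, n_case_samples = 9,
  n_subtypes = 24, n_genes = 500, cells_per_subtype = 25,
  affected_subtypes = data.frame(
    subtype = c("L2_Cux2_a", "Pvalb_a"),
    n_de_genes = c(60, 40), log2fc = c(2, 1.5)),
  composition_shifts = data.frame(subtype = "Vip_a", ratio = 0.45),
  planted_modules = list(
    list(size = 30, loading = 1.2, coupling = 0,
         subtypes = c("L2_Cux2_a", "L2_Cux2_b", "L2_Cux2_c")),
    list(size = 30, loading = 1.2, coupling = 0.5,
         subtypes = c("L2_Cux2_a", "L2_Cux2_b", "L2_Cux2_c")),
    list(size = 30, loading = 1.2, coupling = 0,
         subtypes = c("L2_Cux2_a", "L2_Cux2_b", "L2_Cux2_c"))),
  seed = seed)

ch <- generate_cohort(cfg)
write_counts(ch$data, out)

gs <- generate_gene_sets(ch$truth, n_terms = 60, n_spiked = 8, seed = seed)
write_gmt(gs$gene_sets, file.path(out, "gene_sets.gmt"))
writeLines(gs$curated, file.path(out, "curated_genes.txt"))
writeLines(gs$curated, file.path(out, "gwas_genes.txt"))
writeLines(gs$autopsy, file.path(out, "autopsy_genes.txt"))

fish <- generate_smfish_table(
  n_cells_per_group = c(22, 43), noise = 0.3,
  group_means = list(target = c(1000, 550), reference = 800),
  n_sections = 3, seed = seed)
write.table(fish, file.path(out, "smfish_intensities.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

truth_de <- ch$truth$de
write.table(truth_de, file.path(out, "truth_de.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
mod_tab <- do.call(rbind, lapply(names(ch$truth$modules), function(m)
  data.frame(module = m, gene = ch$truth$modules[[m]]$genes,
             coupling = ch$truth$modules[[m]]$coupling)))
write.table(mod_tab, file.path(out, "truth_modules.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

print(ch$data)
cat("planted DE subtypes:",
    paste(unique(truth_de$subtype), collapse = ", "), "\n")
cat("depleted subtype: Vip_a (case/control ratio 0.45)\n")
cat("planted modules:", length(ch$truth$modules),
    "(module2 condition-coupled)\n")
cat("wrote", out, "\n")
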
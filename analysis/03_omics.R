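#!/usr/bin/env Rscript
# The molecular arm: nCounter-style miRNA differential expression on a
# simulated 578-feature panel (166 robustly expressed, 45 spiked up in the
# case group, n = 5 WT vs 6 case), proteomics-style overlap/proportion
# analysis of two simulated tissue tables (n = 4 per group), and
# counter-regulation pairing against the bundled miRNA -> protein target map.

suppressPackageStartupMessages(library(gutmotion))
dir.create("results", showWarnings = FALSE)
set.seed(439)

## miRNA panel -----------------------------------------------------------------
cm <- simulate_count_matrix(spike_design(seed = 439))
nm <- normalize_counts(cm)
de_mirna <- differential_expression(nm, alpha = 0.05, min_count = 100)
cat(sprintf("miRNA panel: %d/578 robustly expressed (>= 100 counts), %d significant at p <= 0.05\n",
            sum(de_mirna$expressed), sum(de_mirna$significant)))
truth <- attr(cm, "truth")
sens <- mean(de_mirna$significant[match(truth$feature[truth$spiked],
                                        de_mirna$feature)])
cat(sprintf("  %.0f%% of the 45 spiked miRNAs recovered\n", 100 * sens))
write.table(de_mirna, "results/mirna_de.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
vol <- volcano_table(de_mirna, path = "results/mirna_volcano.png")
cat(sprintf("volcano: %d points plotted, %d omitted for missing p\n",
            nrow(vol), attr(vol, "n_omitted")))

## proteomics overlap arithmetic on the published tissue tallies ----------------
# 74 of 1044 detected proteins significantly altered in the SI, 147 in the LI,
# 13 in both: partition and integer proportions
ov <- set_overlap(sprintf("si_%d", 1:74),
                  c(sprintf("si_%d", 1:13), sprintf("li_%d", 1:134)))
cat(sprintf("proteins: %d%% significant in SI, %d%% in LI; partition %d / %d / %d (SI only / LI only / both)\n",
            proportion_significant(74, 1044), proportion_significant(147, 1044),
            ov[["a_only"]], ov[["b_only"]], ov[["both"]]))
jsonlite::write_json(
  list(si_only = ov[["a_only"]], li_only = ov[["b_only"]], both = ov[["both"]],
       pct_si = proportion_significant(74, 1044),
       pct_li = proportion_significant(147, 1044)),
  "results/protein_overlap.json", auto_unbox = TRUE)

## counter-regulation pairing ---------------------------------------------------
# small protein-intensity table: the three candidate markers halved in the
# case group, 17 unaffected proteins, n = 4 per group
target_map <- read_target_map(system.file("extdata", "mirna_target_map.tsv",
                                          package = "gutmotion"))
prot_names <- c("Nefl", "Vamp2", "Calb2", sprintf("null_%02d", 1:17))
mu <- rep(1000, 20)
intens <- sapply(1:8, function(s) {
  m <- mu
  if (s > 4) m[1:3] <- m[1:3] / 2          # markers down in the case group
  round(m * exp(rnorm(20, 0, 0.08)))
})
dimnames(intens) <- list(prot_names, sprintf("%s_%d", rep(c("WT", "case"),
                                                          each = 4), 1:8))
prot_cm <- count_matrix(intens, groups = rep(c("WT", "case"), each = 4),
                        kind = "protein_intensity")
de_prot <- differential_expression(prot_cm, min_count = 0)

# miRNA side: the 16 mapped miRNAs spiked up 2-fold plus 14 unaffected ones
mir_names <- c(unique(target_map$mirna), sprintf("miR-null-%02d", 1:14))
mir_counts <- sapply(1:11, function(s) {
  m <- rep(400, 30)
  if (s > 5) m[1:16] <- m[1:16] * 2
  c(round(m * exp(rnorm(30, 0, 0.1))), Actb = 2000, B2m = 1000)
})
dimnames(mir_counts) <- list(c(mir_names, "Actb", "B2m"),
                             sprintf("%s_%d", rep(c("WT", "case"), c(5, 6)),
                                     1:11))
mir_cm <- count_matrix(mir_counts, groups = rep(c("WT", "case"), c(5, 6)),
                       housekeeping = c("Actb", "B2m"))
de_mir_demo <- differential_expression(normalize_counts(mir_cm))

pairs <- counter_regulation_pairs(de_mir_demo, de_prot, target_map)
cat(sprintf("counter-regulation: %d interactions over %d miRNAs and %d proteins\n",
            pairs$n_interactions, pairs$n_mirnas, pairs$n_proteins))
write.table(pairs$pairs, "results/counter_regulation_pairs.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
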
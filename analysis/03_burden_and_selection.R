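#!/usr/bin/env Rscript
# Step 3 — burden asymmetry and multi-cohort locus selection.
#
# Two analyses over in-memory simulations:
#   (a) the multi-cohort selection flow on the default design (three
#       planted risk deletions), repeated over seeds to estimate how often
#       every planted locus is recovered with no false selections; and
#   (b) the global burden summary on a design that plants risk deletions
#       alongside protective duplications, reproducing the expected
#       direction asymmetry: median OR of significant losses above 1,
#       median OR of significant gains below 1.

suppressMessages(library(cnvburden))

dir.create("results", showWarnings = FALSE)
seed <- 20260928L
n_seeds <- 10L
margin <- 120  # attribution window: 6 x the 20-bp breakpoint jitter SD

## (a) selection recovery over seeds
rows <- lapply(seq_len(n_seeds), function(k) {
  cfg <- simulation_config(seed = seed + k)
  res <- run_simulation_study(cfg)
  rec <- planted_locus_recovery(res$selected, cfg$planted, margin = margin)
  data.frame(seed = seed + k, n_selected_regions = nrow(res$selected),
             n_loci_recovered = sum(rec$recovered),
             n_false_selected = rec$n_false_selected,
             min_primary_or = if (nrow(res$selected))
               min(res$selected$primary_or) else NA_real_,
             min_secondary_or = if (nrow(res$selected))
               min(res$selected$secondary_or) else NA_real_)
})
recovery <- do.call(rbind, rows)
utils::write.table(recovery, "results/selection_recovery.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("selection recovery over", n_seeds, "seeds:\n")
print(recovery, row.names = FALSE)
cat(sprintf("complete recovery (3/3 loci, 0 false) in %d/%d seeds\n\n",
            sum(recovery$n_loci_recovered == 3 &
                  recovery$n_false_selected == 0), n_seeds))

## (b) burden direction asymmetry
cfg_asym <- simulation_config(seed = seed, planted = asymmetry_planted_loci())
res_asym <- run_simulation_study(cfg_asym)
b <- res_asym$burden
print(b)
burden_tab <- data.frame(
  class = c("LOSS", "GAIN"),
  n_significant = c(length(b$loss_or), length(b$gain_or)),
  median_or = c(b$median_loss, b$median_gain),
  ranksum_p = b$ranksum_p)
utils::write.table(burden_tab, "results/burden_summary.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("\nwrote results/selection_recovery.tsv and results/burden_summary.tsv\n")
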
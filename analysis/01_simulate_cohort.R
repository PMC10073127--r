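#!/usr/bin/env Rscript
# Step 1 — simulate the study cohorts and write the on-disk fixture.
#
# Generates the design the analysis targets: a primary cohort of 310 cases
# (two batches of 210 and 100) and 100 controls called by five imperfect
# callers, a 100/100 validation cohort called with CNVnator only, three
# planted risk deletions (carrier frequency 50% in cases vs 15% in
# controls), a group-independent background CNV process, and a
# centromere/telomere/segmental-duplication track. Everything is written
# under scratch/fixture/ in the same formats a real study would provide.

suppressMessages(library(cnvburden))

seed <- 20260928L
fixture_dir <- "scratch/fixture"  # bulky raw fixture; regenerate at will

cfg <- simulation_config(seed = seed)
sim <- write_fixture(cfg, fixture_dir)

sheet <- sim$sheet
truth <- sim$truth
cat("cohort design:\n")
print(table(sheet$group, sheet$cohort))
cat("\ntrue CNV events:", nrow(truth), "\n")
cat("  planted:", sum(truth$origin == "planted"),
    " background:", sum(truth$origin == "background"), "\n")

prim <- sheet[sheet$cohort == "PRIMARY", ]
for (i in seq_len(nrow(cfg$planted))) {
  pl <- cfg$planted[i, ]
  carriers <- truth$sample_id[!is.na(truth$locus_id) &
                                truth$locus_id == pl$locus_id]
  grp <- prim$group[match(carriers, prim$sample_id)]
  cat(sprintf("  locus %s (%s %s:%d-%d): %.1f%% of cases, %.1f%% of controls\n",
              pl$locus_id, pl$event_type, pl$chrom, pl$start, pl$end,
              100 * sum(grp == "CASE", na.rm = TRUE) /
                sum(prim$group == "CASE"),
              100 * sum(grp == "CONTROL", na.rm = TRUE) /
                sum(prim$group == "CONTROL")))
}
cat("\nfixture written to", fixture_dir, "\n")
print(list.files(fixture_dir))
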
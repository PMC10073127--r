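test_that("simulation is deterministic given the seed", {
  cfg <- tiny_config(seed = 5L)
  s1 <- simulate_truth(cfg)
  s2 <- simulate_truth(cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$sheet, s2$sheet)
  m <- cfg$callers[[1]]
  expect_identical(emit_caller_calls(s1, m, seed = 99),
                   emit_caller_calls(s2, m, seed = 99))
  expect_identical(simulate_repeat_track(cfg), simulate_repeat_track(cfg))
  # a different seed changes the draw
  expect_false(identical(simulate_truth(tiny_config(seed = 6L))$truth,
                         s1$truth))
})

test_that("the sheet mirrors the configured cohort design", {
  sheet <- simulate_truth(simulation_config(seed = 1L,
                                            background_rate = 0))$sheet
  tab <- table(sheet$group, sheet$cohort)
  expect_equal(tab["CASE", "PRIMARY"], 310L)
  expect_equal(tab["CONTROL", "PRIMARY"], 100L)
  expect_equal(tab["CASE", "SECONDARY"], 100L)
  expect_equal(tab["CONTROL", "SECONDARY"], 100L)
  expect_equal(sum(sheet$batch == "batch1"), 210L)
  expect_equal(sum(sheet$batch == "batch2"), 100L)
  expect_false(anyDuplicated(sheet$sample_id) > 0)
})

test_that("degenerate carrier frequencies are honored exactly", {
  cfg <- tiny_config()
  cfg$planted$case_freq <- 1.0
  cfg$planted$control_freq <- 0.0
  cfg <- simulation_config(seed = 2L, chrom_lengths = cfg$chrom_lengths,
                           n_case_batch1 = 12L, n_case_batch2 = 8L,
                           n_control_primary = 10L, n_case_secondary = 8L,
                           n_control_secondary = 8L, planted = cfg$planted,
                           background_rate = 0)
  sim <- simulate_truth(cfg)
  planted <- sim$truth[sim$truth$origin == "planted", ]
  grp <- sim$sheet$group[match(planted$sample_id, sim$sheet$sample_id)]
  expect_true(all(grp == "CASE"))
  expect_equal(sort(planted$sample_id),
               sort(sim$sheet$sample_id[sim$sheet$group == "CASE"]))
})

test_that("carrier counts fall in the central binomial band", {
  # case_freq 0.5, 310 primary cases: central 99.9% binomial interval
  lo <- qbinom(5e-4, 310, 0.5)
  hi <- qbinom(1 - 5e-4, 310, 0.5)
  cfg <- simulation_config(seed = 31L, background_rate = 0)
  sim <- simulate_truth(cfg)
  prim_cases <- sim$sheet$sample_id[sim$sheet$group == "CASE" &
                                      sim$sheet$cohort == "PRIMARY"]
  for (loc in cfg$planted$locus_id) {
    carriers <- sum(sim$truth$locus_id == loc &
                      sim$truth$sample_id %in% prim_cases, na.rm = TRUE)
    expect_gte(carriers, lo)
    expect_lte(carriers, hi)
  }
})

test_that("empirical carrier frequency converges to the configured one", {
  cfg <- simulation_config(seed = 77L, n_case_batch1 = 2000L,
                           n_case_batch2 = 0L, n_control_primary = 2000L,
                           n_case_secondary = 0L, n_control_secondary = 0L,
                           planted = default_planted_loci()[1, ],
                           background_rate = 0)
  sim <- simulate_truth(cfg)
  grp <- sim$sheet$group[match(sim$truth$sample_id, sim$sheet$sample_id)]
  f_case <- sum(grp == "CASE") / 2000
  f_ctrl <- sum(grp == "CONTROL") / 2000
  expect_lt(abs(f_case - 0.5), 0.03)
  expect_lt(abs(f_ctrl - 0.15), 0.03)
})

test_that("background events never overlap planted loci or each other", {
  cfg <- tiny_config(seed = 13L, background_rate = 8)
  sim <- simulate_truth(cfg)
  bg <- sim$truth[sim$truth$origin == "background", ]
  pl <- cfg$planted
  hits <- mapply(function(chrom, s, e)
    any(pl$chrom == chrom & pl$start < e & s < pl$end),
    bg$chrom, bg$start, bg$end)
  expect_false(any(hits))
  for (s in unique(bg$sample_id)) {
    ev <- bg[bg$sample_id == s, ]
    for (chr in unique(ev$chrom)) {
      e <- ev[ev$chrom == chr, ]
      e <- e[order(e$start), ]
      if (nrow(e) > 1) expect_true(all(e$start[-1] >= e$end[-nrow(e)]))
    }
  }
})

test_that("a perfect caller reproduces the truth; a blind one emits nothing", {
  cfg <- tiny_config(seed = 3L)
  sim <- simulate_truth(cfg)
  perfect <- caller_model("delly2", sensitivity = 1, fp_rate = 0,
                          jitter_sd = 0)
  calls <- emit_caller_calls(sim, perfect, seed = 1)
  truth <- sim$truth[order(sim$truth$sample_id, sim$truth$chrom,
                           sim$truth$start), ]
  expect_equal(nrow(calls), nrow(truth))
  expect_equal(calls[c("sample_id", "chrom", "start", "end", "event_type")],
               truth[c("sample_id", "chrom", "start", "end", "event_type")],
               ignore_attr = TRUE)
  expect_true(all(is.na(calls$norm_rd)))  # delly2 has no quality fields
  blind <- caller_model("delly2", sensitivity = 0, fp_rate = 0)
  expect_equal(nrow(emit_caller_calls(sim, blind, seed = 1)), 0L)
})

test_that("false-positive totals follow the configured Poisson rate", {
  cfg <- simulation_config(seed = 21L, n_case_batch1 = 100L,
                           n_case_batch2 = 0L, n_control_primary = 0L,
                           n_case_secondary = 0L, n_control_secondary = 0L,
                           planted = default_planted_loci()[0, ],
                           background_rate = 0)
  sim <- simulate_truth(cfg)
  noisy <- caller_model("lumpy", sensitivity = 0.9, fp_rate = 2.0)
  calls <- emit_caller_calls(sim, noisy, seed = 8)
  # all calls are FPs here (no truth); Poisson(200) central 99.9% interval
  expect_gte(nrow(calls), qpois(5e-4, 200))
  expect_lte(nrow(calls), qpois(1 - 5e-4, 200))
})

test_that("jittered breakpoints stay inside the chromosome and ordered", {
  cfg <- tiny_config(seed = 4L, background_rate = 6)
  sim <- simulate_truth(cfg)
  wobbly <- caller_model("cnvnator", sensitivity = 1, fp_rate = 1,
                         jitter_sd = 500)
  calls <- emit_caller_calls(sim, wobbly, seed = 2)
  expect_true(all(calls$start < calls$end))
  expect_true(all(calls$start >= 0))
  expect_true(all(calls$end <= cfg$chrom_lengths[calls$chrom]))
  expect_true(all(calls$q0 >= 0 & calls$q0 <= 1))
  expect_true(all(calls$norm_rd >= 0))
})

test_that("repeat track covers ~repeat_fraction, ends, centre, no planted", {
  pl <- data.frame(locus_id = "del_a", chrom = "chr1", start = 400000L,
                   end = 401000L, event_type = "DEL", case_freq = 0.5,
                   control_freq = 0.1)
  cfg <- simulation_config(seed = 10L, chrom_lengths = c(chr1 = 1e6),
                           planted = pl, repeat_fraction = 0.2)
  track <- simulate_repeat_track(cfg)
  total <- sum(track$end - track$start)
  expect_gte(total, 0.18e6)
  expect_lte(total, 0.22e6)
  expect_true(any(track$start == 0))          # telomere analogue, left
  expect_true(any(track$end == 1e6))          # telomere analogue, right
  expect_false(any(track$start < 401000 & 400000 < track$end))
  # intervals are non-overlapping
  t <- track[order(track$start), ]
  expect_true(all(t$start[-1] >= t$end[-nrow(t)]))
  # zero fraction leaves only the documented 1-bp stubs
  cfg0 <- simulation_config(seed = 10L, chrom_lengths = c(chr1 = 1e6),
                            planted = pl, repeat_fraction = 0)
  stubs <- simulate_repeat_track(cfg0)
  expect_equal(nrow(stubs), 3L)
  expect_true(all(stubs$end - stubs$start == 1))
})

test_that("config validation rejects out-of-bounds or overlapping loci", {
  pl <- default_planted_loci()
  pl$end[1] <- 9e6
  expect_error(simulation_config(planted = pl), "past its chromosome")
  pl <- default_planted_loci()
  pl$chrom[1] <- "chrX"
  expect_error(simulation_config(planted = pl), "missing from chrom_lengths")
  pl <- default_planted_loci()
  pl$start[2] <- pl$start[1]
  pl$end[2] <- pl$end[1] + 10L
  pl$chrom[2] <- pl$chrom[1]
  expect_error(simulation_config(planted = pl), "non-overlapping")
})

test_that("write_fixture emits the full file tree, reproducibly", {
  cfg <- tiny_config(seed = 17L)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_fixture(cfg, dir1)
  write_fixture(cfg, dir2)
  expect_setequal(list.files(dir1),
                  c("samples.tsv", "repeats.bed", "manifest.json",
                    "secondary",
                    sprintf("calls_%s.tsv", c("cnvnator", "gatk_gcnv",
                                              "delly2", "cnmops", "lumpy"))))
  sec_files <- list.files(file.path(dir1, "secondary"))
  expect_length(sec_files, 16L)  # one CNVnator file per secondary sample
  # same seed -> identical manifest bytes
  expect_identical(unname(tools::md5sum(file.path(dir1, "manifest.json"))),
                   unname(tools::md5sum(file.path(dir2, "manifest.json"))))
  # the files parse back with the package readers
  sheet <- read_sample_sheet(file.path(dir1, "samples.tsv"))
  expect_equal(nrow(sheet), 46L)
  calls <- read_calls_tsv(file.path(dir1, "calls_cnvnator.tsv"))
  expect_true(all(calls$caller_id == "cnvnator"))
  one <- read_cnvnator(file.path(dir1, "secondary", sec_files[1]),
                       sub("\\.cnvnator\\.txt$", "", sec_files[1]))
  expect_true(all(one$caller_id == "cnvnator"))
})
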
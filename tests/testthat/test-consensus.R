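test_that("reciprocal overlap matches the analytic values", {
  iv <- function(s, e, chrom = "chr1") data.frame(chrom = chrom, start = s,
                                                  end = e)
  expect_equal(reciprocal_overlap(iv(0, 100), iv(0, 100)), 1.0)
  expect_equal(reciprocal_overlap(iv(0, 100), iv(50, 150)), 0.5)
  expect_equal(reciprocal_overlap(iv(0, 100), iv(10, 110)), 0.9)
  expect_equal(reciprocal_overlap(iv(0, 100), iv(200, 300)), 0)
  expect_equal(reciprocal_overlap(iv(0, 100), iv(0, 100, "chr2")), 0)
  # a tiny call inside a giant one merges one-way but not reciprocally
  expect_lt(reciprocal_overlap(iv(0, 1000), iv(0, 10)), 0.011)
})

test_that("same-type overlapping calls merge into a union-span consensus", {
  calls <- make_calls(
    make_call(caller_id = "cnvnator", start = 100L, end = 200L),
    make_call(caller_id = "delly2", start = 110L, end = 210L))
  cons <- merge_sample_calls(calls)
  expect_equal(nrow(cons), 1L)
  expect_equal(cons$start, 100)
  expect_equal(cons$end, 210)
  expect_equal(cons$support, 2L)
  expect_equal(cons$callers, "cnvnator,delly2")
  # exactly 50% reciprocal overlap does NOT merge (strict > 0.5)
  at_half <- make_calls(
    make_call(caller_id = "cnvnator", start = 0L, end = 100L),
    make_call(caller_id = "delly2", start = 50L, end = 150L))
  expect_equal(nrow(merge_sample_calls(at_half, min_support = 1)), 2L)
  # different event types never merge
  mixed <- make_calls(
    make_call(caller_id = "cnvnator", start = 100L, end = 200L),
    make_call(caller_id = "delly2", start = 100L, end = 200L,
              event_type = "DUP"))
  expect_equal(nrow(merge_sample_calls(mixed, min_support = 1)), 2L)
})

test_that("support counts distinct callers and gates the consensus", {
  solo <- make_call()
  expect_equal(nrow(merge_sample_calls(solo, min_support = 2)), 0L)
  expect_equal(nrow(merge_sample_calls(solo, min_support = 1)), 1L)
  # two calls from the same caller are support 1, not 2
  twice <- make_calls(make_call(start = 100L, end = 200L),
                      make_call(start = 105L, end = 205L))
  cons1 <- merge_sample_calls(twice, min_support = 1)
  expect_equal(cons1$support, 1L)
  expect_equal(cons1$n_members, 2L)
  expect_equal(nrow(merge_sample_calls(twice, min_support = 2)), 0L)
})

test_that("merging chains transitively through connected components", {
  chain <- make_calls(
    make_call(caller_id = "cnvnator", start = 0L, end = 100L),
    make_call(caller_id = "delly2", start = 40L, end = 140L),
    make_call(caller_id = "lumpy", start = 80L, end = 180L))
  # A-B and B-C overlap 0.6; A-C only 0.2; still one component
  cons <- merge_sample_calls(chain)
  expect_equal(nrow(cons), 1L)
  expect_equal(c(cons$start, cons$end), c(0, 180))
  expect_equal(cons$support, 3L)
})

test_that("merging is input-order invariant and idempotent", {
  calls <- random_calls(120, seed = 11)
  calls <- calls[calls$sample_id == calls$sample_id[1], ]
  cons <- merge_sample_calls(calls, min_support = 1)
  for (seed in 1:3) {
    set.seed(seed)
    perm <- calls[sample(nrow(calls)), ]
    cons_p <- merge_sample_calls(perm, min_support = 1)
    expect_equal(cons_p[names(cons_p) != "members"],
                 cons[names(cons) != "members"])
  }
  # consensus-level idempotence: re-merging the consensus intervals as
  # support-1 calls yields the same spans
  again <- merge_calls(data.frame(
    sample_id = cons$sample_id, caller_id = "merged", chrom = cons$chrom,
    start = as.integer(cons$start), end = as.integer(cons$end),
    event_type = cons$event_type, norm_rd = NA_real_, eval1 = NA_real_,
    eval2 = NA_real_, eval3 = NA_real_, eval4 = NA_real_, q0 = NA_real_),
    min_support = 1)
  expect_equal(again[c("chrom", "start", "end", "event_type")],
               cons[c("chrom", "start", "end", "event_type")])
  # lowering min_support never shrinks the consensus set
  expect_gte(nrow(merge_sample_calls(calls, min_support = 1)),
             nrow(merge_sample_calls(calls, min_support = 2)))
  expect_error(merge_sample_calls(random_calls(10, 1)), "single sample")
})

test_that("atomic regions split at every boundary and keep the footprint", {
  cons <- calls_as_consensus(make_calls(
    make_call(sample_id = "s1", start = 100L, end = 300L),
    make_call(sample_id = "s2", start = 200L, end = 400L)))
  reg <- build_atomic_regions(cons)
  expect_equal(reg$start, c(100, 200, 300))
  expect_equal(reg$end, c(200, 300, 400))
  # a single call maps to a single region equal to the call
  one <- build_atomic_regions(calls_as_consensus(make_call()))
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end), c(100, 200))
  # chromosomes segment independently
  two_chr <- calls_as_consensus(make_calls(
    make_call(chrom = "chr1"), make_call(chrom = "chr2")))
  expect_equal(sort(build_atomic_regions(two_chr)$chrom),
               c("chr1", "chr2"))
  # disjoint calls leave a gap (no region over uncovered bp)
  gap <- calls_as_consensus(make_calls(
    make_call(start = 0L, end = 100L),
    make_call(start = 500L, end = 600L)))
  reg <- build_atomic_regions(gap)
  expect_equal(nrow(reg), 2L)
  expect_equal(sum(reg$end - reg$start), 200)
})

test_that("atomic regions conserve consensus footprint bp over random sets", {
  for (seed in 1:5) {
    calls <- random_calls(80, seed = 100 + seed)
    cons <- merge_calls(calls, min_support = 1)
    reg <- build_atomic_regions(cons)
    # disjoint and sorted within chromosome
    for (chr in unique(reg$chrom)) {
      r <- reg[reg$chrom == chr, ]
      expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
    }
    # union of regions == union of consensus intervals, in bp
    by_chr <- split(cons, cons$chrom)
    fp <- sum(vapply(by_chr, function(cc)
      sum(IRanges::width(IRanges::reduce(
        IRanges::IRanges(cc$start + 1, cc$end)))), numeric(1)))
    expect_equal(sum(reg$end - reg$start), fp)
  }
})

test_that("repeat filtering removes regions at >= 50% merged coverage", {
  regions <- build_atomic_regions(calls_as_consensus(
    make_call(start = 0L, end = 100L)))
  rep1 <- data.frame(chrom = "chr1", start = 0L, end = 50L)
  expect_equal(nrow(filter_regions_by_repeats(regions, rep1)), 0L)
  rep2 <- data.frame(chrom = "chr1", start = 0L, end = 49L)
  expect_equal(nrow(filter_regions_by_repeats(regions, rep2)), 1L)
  # overlapping repeat intervals are merged before measuring coverage
  rep3 <- data.frame(chrom = "chr1", start = c(0L, 20L), end = c(30L, 60L))
  expect_equal(nrow(filter_regions_by_repeats(regions, rep3)), 0L)
  # a repeat on another chromosome never counts
  rep4 <- data.frame(chrom = "chr2", start = 0L, end = 100L)
  expect_equal(nrow(filter_regions_by_repeats(regions, rep4)), 1L)
})

test_that("copy states classify LOSS/GAIN/CONFLICT/NEUTRAL per sample", {
  cons <- calls_as_consensus(make_calls(
    make_call(sample_id = "case01", start = 100L, end = 400L),
    make_call(sample_id = "case02", start = 100L, end = 400L,
              event_type = "DUP"),
    make_call(sample_id = "case03", start = 100L, end = 400L),
    make_call(sample_id = "case03", start = 150L, end = 420L,
              event_type = "DUP")))
  regions <- build_atomic_regions(cons)
  sheet <- tiny_sheet()
  csm <- assign_copy_states(regions, cons, sheet$sample_id)
  mid <- regions$region_id[regions$start == 150]
  expect_equal(copy_state(csm, mid, "case01"), "LOSS")
  expect_equal(copy_state(csm, mid, "case02"), "GAIN")
  expect_equal(copy_state(csm, mid, "case03"), "CONFLICT")
  expect_equal(copy_state(csm, mid, "ctrl01"), "NEUTRAL")
  m <- as.matrix(csm)
  expect_equal(dim(m), c(nrow(regions), 8L))
  expect_true(all(m %in% c("NEUTRAL", "LOSS", "GAIN", "CONFLICT")))
})

test_that("copy-state assignment rejects regions from a foreign consensus", {
  cons <- calls_as_consensus(make_call(start = 100L, end = 400L))
  foreign <- data.frame(region_id = "chr1:50-150", chrom = "chr1",
                        start = 50, end = 150,
                        stringsAsFactors = FALSE)
  expect_error(assign_copy_states(foreign, cons, "s1"),
               "partially overlaps")
})
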
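# Independent oracles and small fixture builders shared across tests.

# Fisher two-sided p by brute-force enumeration over the full table support,
# using only choose() arithmetic (independent of dhyper and of the package).
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b
  r2 <- c + d
  k <- a + c
  n <- r1 + r2
  support <- max(0, k - r2):min(k, r1)
  prob <- choose(r1, support) * choose(r2, k - support) / choose(n, k)
  p_obs <- choose(r1, a) * choose(r2, k - a) / choose(n, k)
  min(1, sum(prob[prob <= p_obs * (1 + 1e-7)]))
}

# one CNV call row with sensible defaults
make_call <- function(sample_id = "s1", caller_id = "cnvnator",
                      chrom = "chr1", start = 100L, end = 200L,
                      event_type = "DEL", norm_rd = 0.5, eval1 = 1e-6,
                      eval2 = 1e-6, eval3 = 1, eval4 = 1, q0 = 0.1) {
  data.frame(sample_id = sample_id, caller_id = caller_id, chrom = chrom,
             start = as.integer(start), end = as.integer(end),
             event_type = event_type, norm_rd = norm_rd, eval1 = eval1,
             eval2 = eval2, eval3 = eval3, eval4 = eval4, q0 = q0,
             stringsAsFactors = FALSE)
}

make_calls <- function(...) do.call(rbind, list(...))

# random but valid call table for round-trip / fuzz properties
random_calls <- function(n, seed) {
  set.seed(seed)
  chrom <- sample(c("chr1", "chr2"), n, replace = TRUE)
  start <- sample.int(1e6, n)
  width <- sample.int(5000, n) + 49L
  quality <- runif(n) < 0.6
  data.frame(sample_id = sample(sprintf("s%02d", 1:8), n, replace = TRUE),
             caller_id = sample(c("cnvnator", "delly2", "lumpy"), n,
                                replace = TRUE),
             chrom = chrom, start = start, end = start + width,
             event_type = sample(c("DEL", "DUP"), n, replace = TRUE),
             norm_rd = ifelse(quality, runif(n, 0, 2), NA_real_),
             eval1 = ifelse(quality, runif(n) * 10^-runif(n, 0, 8),
                            NA_real_),
             eval2 = ifelse(quality, runif(n) * 10^-runif(n, 0, 8),
                            NA_real_),
             eval3 = ifelse(quality, runif(n), NA_real_),
             eval4 = ifelse(quality, runif(n), NA_real_),
             q0 = ifelse(quality,
                         ifelse(runif(n) < 0.1, -1, runif(n)), NA_real_),
             stringsAsFactors = FALSE)
}

# small sample sheet covering both cohorts
tiny_sheet <- function(n_case = 4, n_ctrl = 4) {
  data.frame(
    sample_id = c(sprintf("case%02d", seq_len(n_case)),
                  sprintf("ctrl%02d", seq_len(n_ctrl))),
    group = rep(c("CASE", "CONTROL"), c(n_case, n_ctrl)),
    cohort = "PRIMARY",
    batch = rep(c("batch1", "hc"), c(n_case, n_ctrl)),
    stringsAsFactors = FALSE)
}

# a fast, tiny simulation configuration for property checks
tiny_config <- function(seed = 1L, background_rate = 2, ...) {
  simulation_config(
    seed = seed,
    background_rate = background_rate,
    chrom_lengths = c(chr1 = 1e6, chr2 = 1e6),
    n_case_batch1 = 12L, n_case_batch2 = 8L, n_control_primary = 10L,
    n_case_secondary = 8L, n_control_secondary = 8L,
    planted = data.frame(locus_id = "del_a", chrom = "chr1",
                         start = 400000L, end = 401000L, event_type = "DEL",
                         case_freq = 0.5, control_freq = 0.15,
                         stringsAsFactors = FALSE), ...)
}
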
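# Synthetic cohort + callset generator.
#
# Emulates the study design the analysis assumes: a primary case-control
# cohort in two case batches plus an independent validation cohort, planted
# deletion/duplication loci with group-specific carrier frequencies, a
# group-independent background CNV process, several imperfect callers with
# breakpoint jitter and false calls, and CNVnator-style quality fields.
# Carriers are heterozygous: one-copy loss (norm_rd ~ 0.5) or one-copy gain
# (norm_rd ~ 1.5).

#' Describe an imperfect CNV caller
#'
#' @param caller_id Caller name token.
#' @param sensitivity Per-true-event detection probability.
#' @param fp_rate Mean false calls per sample (Poisson).
#' @param jitter_sd Breakpoint noise SD in bp; applied independently to both
#'   breakpoints as a rounded Normal(0, jitter_sd).
#' @param rd_loss_mean,rd_loss_sd Normalized read depth distribution for a
#'   one-copy loss (diploid is ~1.0).
#' @param rd_gain_mean,rd_gain_sd Normalized read depth distribution for a
#'   one-copy gain.
#' @param q0_alpha,q0_beta Beta parameters for the fraction of zero
#'   mapping-quality reads.
#' @param eval_scale Upper bound of the (uniform) e-value draw for true
#'   calls; half of false calls draw large e-values instead, so the CNVnator
#'   e-value filter removes some of them.
#' @param emits_quality Whether the caller reports `norm_rd`/e-values/`q0`
#'   (CNVnator does; the other callers leave them null).
#' @return A `caller_model` list.
#' @export
caller_model <- function(caller_id, sensitivity = 0.9, fp_rate = 1.0,
                         jitter_sd = 20, rd_loss_mean = 0.5,
                         rd_loss_sd = 0.05, rd_gain_mean = 1.5,
                         rd_gain_sd = 0.10, q0_alpha = 1, q0_beta = 9,
                         eval_scale = 1e-4,
                         emits_quality = identical(caller_id, "cnvnator")) {
  stopifnot(sensitivity >= 0, sensitivity <= 1, fp_rate >= 0, jitter_sd >= 0,
            rd_loss_sd >= 0, rd_gain_sd >= 0, q0_alpha > 0, q0_beta > 0,
            eval_scale > 0)
  structure(list(caller_id = caller_id, sensitivity = sensitivity,
                 fp_rate = fp_rate, jitter_sd = jitter_sd,
                 rd_loss_mean = rd_loss_mean, rd_loss_sd = rd_loss_sd,
                 rd_gain_mean = rd_gain_mean, rd_gain_sd = rd_gain_sd,
                 q0_alpha = q0_alpha, q0_beta = q0_beta,
                 eval_scale = eval_scale, emits_quality = emits_quality),
            class = "caller_model")
}

#' Default five-caller panel
#'
#' One read-depth caller with CNVnator-style quality fields plus four
#' callers modelled on split-read/discordant-pair and alternative
#' depth-based tools, which report interval and type only.
#'
#' @param sensitivity,fp_rate,jitter_sd Shared noise settings for all five.
#' @return List of five [caller_model()] objects.
#' @export
default_callers <- function(sensitivity = 0.9, fp_rate = 1.0, jitter_sd = 20) {
  ids <- c("cnvnator", "gatk_gcnv", "delly2", "cnmops", "lumpy")
  lapply(ids, caller_model, sensitivity = sensitivity, fp_rate = fp_rate,
         jitter_sd = jitter_sd)
}

#' Default planted risk-deletion loci
#'
#' Three non-overlapping ~1.2-1.5 kb deletions carried by 50% of cases and
#' 15% of controls, the carrier-frequency contrast the association stage is
#' designed to detect.
#'
#' @return Data frame of planted loci.
#' @export
default_planted_loci <- function() {
  data.frame(locus_id = c("del_chr1_a", "del_chr1_b", "del_chr2_a"),
             chrom = c("chr1", "chr1", "chr2"),
             start = c(1000000L, 3000000L, 2000000L),
             end = c(1001331L, 3001200L, 2001500L),
             event_type = "DEL", case_freq = 0.5, control_freq = 0.15,
             stringsAsFactors = FALSE)
}

#' Planted design with risk deletions and protective gains
#'
#' Four risk deletions (carrier frequency 0.5 in cases vs 0.15 in controls)
#' and four protective duplications (0.05 vs 0.30), used to probe the
#' direction asymmetry of the burden summary.
#'
#' @return Data frame of planted loci.
#' @export
asymmetry_planted_loci <- function() {
  data.frame(
    locus_id = c("del_a", "del_b", "del_c", "del_d",
                 "dup_a", "dup_b", "dup_c", "dup_d"),
    chrom = c("chr1", "chr1", "chr2", "chr2", "chr1", "chr1", "chr2", "chr2"),
    start = c(1000000L, 3000000L, 2000000L, 4000000L,
              2000000L, 4000000L, 1000000L, 3000000L),
    end = c(1001331L, 3001200L, 2001500L, 4001250L,
            2001400L, 4001300L, 1001350L, 3001450L),
    event_type = rep(c("DEL", "DUP"), each = 4L),
    case_freq = rep(c(0.5, 0.05), each = 4L),
    control_freq = rep(c(0.15, 0.30), each = 4L),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defaults mirror the study design the pipeline targets: a primary cohort
#' of 210 + 100 cases in two batches and 100 controls, an independent
#' 100/100 validation cohort, five imperfect callers, and three planted risk
#' deletions on a 2 x 5 Mb desk-scale genome.
#'
#' @param seed Integer seed; every random draw derives from it.
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param n_case_batch1,n_case_batch2,n_control_primary Primary cohort sizes.
#' @param n_case_secondary,n_control_secondary Validation cohort sizes.
#' @param planted Planted locus data frame (`locus_id`, `chrom`, `start`,
#'   `end`, `event_type`, `case_freq`, `control_freq`); loci must be
#'   pairwise non-overlapping and inside the genome.
#' @param background_rate Mean group-independent true background CNVs per
#'   sample (Poisson) — a built-in null.
#' @param background_len_logmean,background_len_logsd Log-normal length
#'   parameters of background events (bp).
#' @param repeat_fraction Fraction of each chromosome covered by the
#'   simulated centromere/telomere/segmental-duplication track, in
#'   \[0, 0.5\].
#' @param callers List of [caller_model()] objects; must contain
#'   `"cnvnator"`, the only caller applied to the validation cohort.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              chrom_lengths = c(chr1 = 5e6, chr2 = 5e6),
                              n_case_batch1 = 210L, n_case_batch2 = 100L,
                              n_control_primary = 100L,
                              n_case_secondary = 100L,
                              n_control_secondary = 100L,
                              planted = default_planted_loci(),
                              background_rate = 5,
                              background_len_logmean = log(1500),
                              background_len_logsd = 0.6,
                              repeat_fraction = 0.1,
                              callers = default_callers()) {
  stopifnot(length(chrom_lengths) >= 1, !is.null(names(chrom_lengths)),
            all(chrom_lengths > 0),
            n_case_batch1 >= 0, n_case_batch2 >= 0, n_control_primary >= 0,
            n_case_secondary >= 0, n_control_secondary >= 0,
            background_rate >= 0, background_len_logsd >= 0,
            repeat_fraction >= 0, repeat_fraction <= 0.5)
  seed <- as.integer(seed)
  if (nrow(planted)) {
    stopifnot(all(planted$case_freq >= 0 & planted$case_freq <= 1),
              all(planted$control_freq >= 0 & planted$control_freq <= 1),
              all(planted$event_type %in% EVENT_TYPES))
    .check_intervals(planted$start, planted$end, "planted locus")
    if (!all(planted$chrom %in% names(chrom_lengths))) {
      stop("planted locus on a chromosome missing from chrom_lengths")
    }
    if (any(planted$end > chrom_lengths[planted$chrom])) {
      stop("planted locus extends past its chromosome end")
    }
    gr <- .as_gr(planted$chrom, planted$start, planted$end)
    if (length(IRanges::findOverlaps(gr, drop.self = TRUE,
                                     drop.redundant = TRUE))) {
      stop("planted loci must be pairwise non-overlapping")
    }
  }
  ids <- vapply(callers, `[[`, character(1), "caller_id")
  if (anyDuplicated(ids)) stop("duplicate caller_id in caller panel")
  structure(list(seed = seed, chrom_lengths = chrom_lengths,
                 n_case_batch1 = as.integer(n_case_batch1),
                 n_case_batch2 = as.integer(n_case_batch2),
                 n_control_primary = as.integer(n_control_primary),
                 n_case_secondary = as.integer(n_case_secondary),
                 n_control_secondary = as.integer(n_control_secondary),
                 planted = planted, background_rate = background_rate,
                 background_len_logmean = background_len_logmean,
                 background_len_logsd = background_len_logsd,
                 repeat_fraction = repeat_fraction, callers = callers),
            class = "sim_config")
}

#' Noiseless study configuration
#'
#' The exact-recovery limit used by identity tests: perfect sensitivity, no
#' breakpoint jitter, no false calls, and quality fields drawn so that the
#' CNVnator quality filter never removes a true call (q0 ~ Beta(1, 99),
#' e-values below 1e-6).
#'
#' @param ... Passed on to [simulation_config()].
#' @return A `sim_config`.
#' @export
noiseless_config <- function(...) {
  callers <- lapply(c("cnvnator", "gatk_gcnv", "delly2", "cnmops", "lumpy"),
                    caller_model, sensitivity = 1, fp_rate = 0, jitter_sd = 0,
                    q0_alpha = 1, q0_beta = 99, eval_scale = 1e-6)
  simulation_config(callers = callers, ...)
}

.make_sheet <- function(config) {
  grp <- function(prefix, n, group, cohort, batch) {
    if (n == 0) {
      return(data.frame(sample_id = character(0), group = character(0),
                        cohort = character(0), batch = character(0),
                        stringsAsFactors = FALSE))
    }
    data.frame(sample_id = sprintf("%s_%03d", prefix, seq_len(n)),
               group = group, cohort = cohort, batch = batch,
               stringsAsFactors = FALSE)
  }
  rbind(grp("case_b1", config$n_case_batch1, "CASE", "PRIMARY", "batch1"),
        grp("case_b2", config$n_case_batch2, "CASE", "PRIMARY", "batch2"),
        grp("ctrl_p", config$n_control_primary, "CONTROL", "PRIMARY", "hc"),
        grp("case_s", config$n_case_secondary, "CASE", "SECONDARY", "batch_s"),
        grp("ctrl_s", config$n_control_secondary, "CONTROL", "SECONDARY",
            "hc_s"))
}

#' Simulate ground-truth CNV events and the sample sheet
#'
#' Each sample carries each planted locus independently with its group's
#' carrier frequency; background events are placed uniformly with log-normal
#' lengths and resampled if they would overlap a planted locus or another of
#' the same sample's events. Identical configs give identical output.
#'
#' @param config A [simulation_config()].
#' @return List with `truth` (data frame `sample_id`, `chrom`, `start`,
#'   `end`, `event_type`, `origin`, `locus_id`), `sheet`, and the `config`.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  sheet <- .make_sheet(config)
  n_samp <- nrow(sheet)
  chroms <- names(config$chrom_lengths)
  lens <- config$chrom_lengths

  rows <- list()
  planted <- config$planted
  if (!is.null(planted) && nrow(planted)) {
    for (i in seq_len(nrow(planted))) {
      freq <- ifelse(sheet$group == "CASE", planted$case_freq[i],
                     planted$control_freq[i])
      carrier <- stats::rbinom(n_samp, 1L, freq) == 1L
      if (any(carrier)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sheet$sample_id[carrier], chrom = planted$chrom[i],
          start = planted$start[i], end = planted$end[i],
          event_type = planted$event_type[i], origin = "planted",
          locus_id = planted$locus_id[i], stringsAsFactors = FALSE)
      }
    }
  }

  if (config$background_rate > 0) {
    chrom_w <- lens / sum(lens)
    has_planted <- nrow(planted) > 0
    for (s in seq_len(n_samp)) {
      k <- stats::rpois(1L, config$background_rate)
      if (k == 0) next
      acc_chrom <- character(k)
      acc_start <- numeric(k)
      acc_end <- numeric(k)
      got <- 0L
      for (j in seq_len(k)) {
        for (try in seq_len(100L)) {
          chrom <- sample(chroms, 1L, prob = chrom_w)
          L <- lens[[chrom]]
          len <- min(max(50, round(stats::rlnorm(
            1L, config$background_len_logmean,
            config$background_len_logsd))), floor(L / 10))
          start <- floor(stats::runif(1L, 0, L - len))
          end <- start + len
          clash <- has_planted &&
            any(planted$chrom == chrom & planted$start < end &
                  start < planted$end)
          if (!clash && got > 0L) {
            ix <- seq_len(got)
            clash <- any(acc_chrom[ix] == chrom & acc_start[ix] < end &
                           start < acc_end[ix])
          }
          if (!clash) {
            got <- got + 1L
            acc_chrom[got] <- chrom
            acc_start[got] <- start
            acc_end[got] <- end
            break
          }
          if (try == 100L) {
            stop("could not place a background event without overlap; ",
                 "background_rate or lengths too large for the genome")
          }
        }
      }
      if (got > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sheet$sample_id[s], chrom = acc_chrom,
          start = as.integer(acc_start), end = as.integer(acc_end),
          event_type = sample(EVENT_TYPES, got, replace = TRUE),
          origin = "background", locus_id = NA_character_,
          stringsAsFactors = FALSE)
      }
    }
  }

  truth <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(sample_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0),
               event_type = character(0), origin = character(0),
               locus_id = character(0), stringsAsFactors = FALSE)
  }
  truth <- truth[order(truth$sample_id, truth$chrom, truth$start,
                       truth$end), , drop = FALSE]
  rownames(truth) <- NULL
  structure(list(truth = truth, sheet = sheet, config = config),
            class = "cnv_sim")
}

#' Emit one caller's noisy callset from simulated truth
#'
#' Each true event is detected with the model's sensitivity; detected
#' breakpoints are independently perturbed by a rounded Normal(0, jitter_sd)
#' and clamped to the chromosome keeping `start < end`. Quality-emitting
#' callers draw `norm_rd` from the loss/gain depth model (truncated at 0),
#' `q0` from its Beta, and small e-values for true calls. False calls follow
#' a per-sample Poisson(`fp_rate`), are placed uniformly, and draw large
#' e-values with probability 0.5.
#'
#' @param sim Output of [simulate_truth()].
#' @param model A [caller_model()].
#' @param seed Integer seed for this caller's noise.
#' @param samples Optional sample ids to emit for (default: all).
#' @return A call data frame.
#' @export
emit_caller_calls <- function(sim, model, seed, samples = NULL) {
  stopifnot(inherits(sim, "cnv_sim"), inherits(model, "caller_model"))
  set.seed(as.integer(seed))
  lens <- sim$config$chrom_lengths
  sample_set <- if (is.null(samples)) sim$sheet$sample_id else samples
  tr <- sim$truth[sim$truth$sample_id %in% sample_set, , drop = FALSE]
  n <- nrow(tr)

  out <- empty_calls()
  if (n > 0) {
    det <- stats::runif(n) < model$sensitivity
    js <- round(stats::rnorm(n, 0, model$jitter_sd))
    je <- round(stats::rnorm(n, 0, model$jitter_sd))
    s2 <- pmax(0, tr$start + js)
    e2 <- pmin(lens[tr$chrom], tr$end + je)
    bad <- s2 >= e2
    s2[bad] <- pmax(0, e2[bad] - 1)
    bad <- s2 >= e2
    e2[bad] <- s2[bad] + 1
    qual <- .draw_quality(model, tr$event_type, n, fp = FALSE)
    keep <- which(det)
    if (length(keep)) {
      out <- data.frame(sample_id = tr$sample_id[keep],
                        caller_id = model$caller_id, chrom = tr$chrom[keep],
                        start = as.integer(s2[keep]),
                        end = as.integer(e2[keep]),
                        event_type = tr$event_type[keep],
                        norm_rd = qual$norm_rd[keep],
                        eval1 = qual$eval1[keep], eval2 = qual$eval2[keep],
                        eval3 = qual$eval3[keep], eval4 = qual$eval4[keep],
                        q0 = qual$q0[keep], stringsAsFactors = FALSE)
    }
  }

  if (model$fp_rate > 0 && length(sample_set)) {
    nf <- stats::rpois(length(sample_set), model$fp_rate)
    total <- sum(nf)
    if (total > 0) {
      chroms <- names(lens)
      chrom <- sample(chroms, total, replace = TRUE, prob = lens / sum(lens))
      len <- pmin(pmax(50, round(stats::rlnorm(
        total, sim$config$background_len_logmean,
        sim$config$background_len_logsd))), floor(lens[chrom] / 10))
      start <- floor(stats::runif(total, 0, lens[chrom] - len))
      type <- sample(EVENT_TYPES, total, replace = TRUE)
      qual <- .draw_quality(model, type, total, fp = TRUE)
      fp <- data.frame(sample_id = rep(sample_set, nf),
                       caller_id = model$caller_id, chrom = chrom,
                       start = as.integer(start),
                       end = as.integer(start + len), event_type = type,
                       norm_rd = qual$norm_rd, eval1 = qual$eval1,
                       eval2 = qual$eval2, eval3 = qual$eval3,
                       eval4 = qual$eval4, q0 = qual$q0,
                       stringsAsFactors = FALSE)
      out <- rbind(out, fp)
    }
  }

  out <- out[order(out$sample_id, out$chrom, out$start, out$end), ,
             drop = FALSE]
  rownames(out) <- NULL
  validate_calls(out)
  out
}

.draw_quality <- function(model, event_type, n, fp = FALSE) {
  if (!model$emits_quality || n == 0) {
    return(list(norm_rd = rep(NA_real_, n), eval1 = rep(NA_real_, n),
                eval2 = rep(NA_real_, n), eval3 = rep(NA_real_, n),
                eval4 = rep(NA_real_, n), q0 = rep(NA_real_, n)))
  }
  rd <- ifelse(event_type == "DEL",
               stats::rnorm(n, model$rd_loss_mean, model$rd_loss_sd),
               stats::rnorm(n, model$rd_gain_mean, model$rd_gain_sd))
  rd <- pmax(rd, 0)
  q0 <- stats::rbeta(n, model$q0_alpha, model$q0_beta)
  draw_eval <- function() stats::runif(n, 0, model$eval_scale)
  if (fp) {
    big <- stats::runif(n) < 0.5
    mk <- function() ifelse(big, stats::runif(n, 0.01, 1), draw_eval())
    list(norm_rd = rd, eval1 = mk(), eval2 = mk(), eval3 = mk(), eval4 = mk(),
         q0 = q0)
  } else {
    list(norm_rd = rd, eval1 = draw_eval(), eval2 = draw_eval(),
         eval3 = draw_eval(), eval4 = draw_eval(), q0 = q0)
  }
}

#' Simulate a centromere/telomere/segmental-duplication track
#'
#' Per chromosome: a telomere block at each end, one central centromere
#' block, and random segmental-duplication blocks, totalling about
#' `repeat_fraction` of the chromosome. The track never overlaps a planted
#' locus. With `repeat_fraction = 0` only 1-bp end and centre stubs remain.
#'
#' @param config A [simulation_config()].
#' @return Data frame `chrom`, `start`, `end` of non-overlapping intervals.
#' @export
simulate_repeat_track <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed((config$seed + 7L) %% .Machine$integer.max)
  planted <- config$planted
  out <- list()
  for (chrom in names(config$chrom_lengths)) {
    L <- config$chrom_lengths[[chrom]]
    budget <- round(config$repeat_fraction * L)
    tel <- max(1L, as.integer(floor(budget * 0.15)))
    cen <- max(1L, as.integer(floor(budget * 0.2)))
    pl <- planted[planted$chrom == chrom, , drop = FALSE]
    overlaps_planted <- function(s, e) {
      nrow(pl) > 0 && any(pl$start < e & s < pl$end)
    }
    acc <- data.frame(start = c(0, L - tel), end = c(tel, L))
    if (overlaps_planted(0, tel) || overlaps_planted(L - tel, L)) {
      stop("telomere blocks would overlap a planted locus on ", chrom)
    }
    cen_s <- NA
    for (off in unique(c(0, seq_len(50L) * cen, -seq_len(50L) * cen))) {
      s <- floor(L / 2 - cen / 2) + off
      if (s < tel || s + cen > L - tel) next
      if (!overlaps_planted(s, s + cen) &&
          !any(acc$start < s + cen & s < acc$end)) {
        cen_s <- s
        break
      }
    }
    if (is.na(cen_s)) {
      stop("could not place the centromere block on ", chrom,
           "; repeat_fraction incompatible with planted loci")
    }
    acc <- rbind(acc, data.frame(start = cen_s, end = cen_s + cen))
    seg_total <- max(0L, budget - 2L * tel - cen)
    if (seg_total > 0) {
      n_seg <- 8L
      sizes <- rep(seg_total %/% n_seg, n_seg)
      sizes[1] <- sizes[1] + seg_total %% n_seg
      sizes <- sizes[sizes > 0]
      for (w in sizes) {
        placed <- FALSE
        for (try in seq_len(500L)) {
          s <- floor(stats::runif(1L, 0, L - w))
          e <- s + w
          if (!overlaps_planted(s, e) &&
              !any(acc$start < e & s < acc$end)) {
            acc <- rbind(acc, data.frame(start = s, end = e))
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          stop("could not place segmental-duplication blocks on ", chrom,
               "; repeat_fraction incompatible with planted loci")
        }
      }
    }
    acc <- acc[order(acc$start), , drop = FALSE]
    out[[chrom]] <- data.frame(chrom = chrom, start = as.integer(acc$start),
                               end = as.integer(acc$end),
                               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a complete simulated fixture to disk
#'
#' Produces the on-disk inputs the pipeline consumes: `samples.tsv`,
#' `repeats.bed`, one generic calls TSV per caller for the primary cohort,
#' one CNVnator-dialect file per validation-cohort sample (the validation
#' cohort is called with CNVnator only), and a JSON manifest recording the
#' seed, the configuration, and the truth table.
#'
#' @param config A [simulation_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the simulation object from [simulate_truth()].
#' @export
write_fixture <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outdir, "secondary"), showWarnings = FALSE)
  sim <- simulate_truth(config)
  repeats <- simulate_repeat_track(config)
  write_sample_sheet(sim$sheet, file.path(outdir, "samples.tsv"))
  write_bed(repeats, file.path(outdir, "repeats.bed"))
  prim <- sim$sheet$sample_id[sim$sheet$cohort == "PRIMARY"]
  sec <- sim$sheet$sample_id[sim$sheet$cohort == "SECONDARY"]
  for (i in seq_along(config$callers)) {
    m <- config$callers[[i]]
    calls <- emit_caller_calls(sim, m, seed = .sub_seed(config$seed, 100L + i),
                               samples = prim)
    write_calls_tsv(calls, file.path(outdir,
                                     sprintf("calls_%s.tsv", m$caller_id)))
  }
  cn <- .cnvnator_model(config)
  sec_calls <- emit_caller_calls(sim, cn, seed = .sub_seed(config$seed, 200L),
                                 samples = sec)
  for (s in sec) {
    write_cnvnator(sec_calls[sec_calls$sample_id == s, , drop = FALSE],
                   file.path(outdir, "secondary",
                             sprintf("%s.cnvnator.txt", s)))
  }
  manifest <- list(seed = config$seed,
                   config = config[setdiff(names(config), "callers")],
                   callers = lapply(config$callers, unclass),
                   truth = sim$truth)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sim)
}

.sub_seed <- function(seed, k) (as.integer(seed) + as.integer(k)) %%
  .Machine$integer.max

.cnvnator_model <- function(config) {
  ids <- vapply(config$callers, `[[`, character(1), "caller_id")
  i <- match("cnvnator", ids)
  if (is.na(i)) stop("caller panel has no 'cnvnator' model; the validation ",
                     "cohort is called with CNVnator only")
  config$callers[[i]]
}
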
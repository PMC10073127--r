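# Multi-cohort locus selection and pipeline orchestration.
#
# A locus survives when it is significant in the whole primary cohort,
# nominally significant with a concordant direction in each case batch
# tested against the primary controls, and validated (same direction,
# nominal significance) at the matched region in the CNVnator-only
# validation cohort. Validation regions are matched to primary regions by
# reciprocal overlap > 0.5, the same rule as call merging.

#' Thresholds of the multi-cohort selection gates
#'
#' @param p_primary Whole-primary-cohort Fisher threshold (default 1e-5).
#' @param p_batch Per-batch nominal threshold (default 0.05).
#' @param p_secondary Validation-cohort threshold (default 0.05).
#' @param require_direction_concordance Require the batch and validation
#'   odds ratios to share the primary direction (default `TRUE`).
#' @param match_overlap Reciprocal-overlap threshold (strict) for matching
#'   validation regions to primary regions.
#' @return A `selection_params` list.
#' @export
selection_params <- function(p_primary = 1e-5, p_batch = 0.05,
                             p_secondary = 0.05,
                             require_direction_concordance = TRUE,
                             match_overlap = 0.5) {
  stopifnot(p_primary > 0, p_batch > 0, p_batch <= 1, p_secondary > 0,
            p_secondary <= 1, p_primary <= p_batch, match_overlap > 0,
            match_overlap <= 1)
  structure(list(p_primary = p_primary, p_batch = p_batch,
                 p_secondary = p_secondary,
                 require_direction_concordance =
                   isTRUE(require_direction_concordance),
                 match_overlap = match_overlap),
            class = "selection_params")
}

# best secondary match (same event type, reciprocal overlap > threshold)
# for each candidate row; NA where none qualifies
.match_secondary <- function(cand, secondary, min_overlap) {
  m <- rep(NA_integer_, nrow(cand))
  if (!nrow(cand) || !nrow(secondary)) return(m)
  cand_gr <- .as_gr(cand$chrom, cand$start, cand$end)
  sec_gr <- .as_gr(secondary$chrom, secondary$start, secondary$end)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(cand_gr, sec_gr))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  same_type <- cand$event_type[q] == secondary$event_type[s]
  q <- q[same_type]
  s <- s[same_type]
  if (!length(q)) return(m)
  ov <- pmin(cand$end[q], secondary$end[s]) -
    pmax(cand$start[q], secondary$start[s])
  ro <- pmin(ov / (cand$end[q] - cand$start[q]),
             ov / (secondary$end[s] - secondary$start[s]))
  ok <- ro > min_overlap
  q <- q[ok]
  s <- s[ok]
  ro <- ro[ok]
  if (!length(q)) return(m)
  ord <- order(q, -ro)
  first <- !duplicated(q[ord])
  m[q[ord][first]] <- s[ord][first]
  m
}

.empty_selection <- function() {
  data.frame(region_id = character(0), chrom = character(0),
             start = numeric(0), end = numeric(0), event_type = character(0),
             primary_p = numeric(0), primary_or = numeric(0),
             direction = character(0), batch1_p = numeric(0),
             batch1_or = numeric(0), batch2_p = numeric(0),
             batch2_or = numeric(0), secondary_region_id = character(0),
             secondary_p = numeric(0), secondary_or = numeric(0),
             stringsAsFactors = FALSE)
}

#' Multi-cohort locus selection
#'
#' Applies the selection flow: primary `p < p_primary`; each batch-vs-control
#' test `p < p_batch` (with the primary odds-ratio direction when
#' concordance is required); and a validation-cohort region matched by
#' reciprocal overlap with `p < p_secondary` (same direction). An unmatched
#' validation region simply fails the gate. Tightening any threshold can
#' only shrink the selection.
#'
#' @param primary_results,batch1_results,batch2_results Association results
#'   over the same primary atomic regions (whole cohort, batch 1 + controls,
#'   batch 2 + controls).
#' @param secondary_results Association results over the validation
#'   cohort's own regions.
#' @param params A [selection_params()].
#' @return Selected loci sorted by primary p: region coordinates, event
#'   type, and p/OR for primary, both batches, and the matched validation
#'   region.
#' @export
select_loci <- function(primary_results, batch1_results, batch2_results,
                        secondary_results, params = selection_params()) {
  stopifnot(inherits(params, "selection_params"))
  cand <- primary_results[primary_results$p_value < params$p_primary, ,
                          drop = FALSE]
  if (!nrow(cand)) return(.empty_selection())
  key <- function(df) paste(df$region_id, df$event_type)
  b1 <- batch1_results[match(key(cand), key(batch1_results)), , drop = FALSE]
  b2 <- batch2_results[match(key(cand), key(batch2_results)), , drop = FALSE]
  sec_i <- .match_secondary(cand, secondary_results, params$match_overlap)
  sec <- secondary_results[sec_i, , drop = FALSE]

  gate <- function(res) {
    ok <- !is.na(res$p_value) & res$p_value < params$p_batch
    if (params$require_direction_concordance) {
      ok <- ok & !is.na(res$direction) & res$direction == cand$direction
    }
    ok
  }
  ok <- gate(b1) & gate(b2) &
    !is.na(sec$p_value) & sec$p_value < params$p_secondary
  if (params$require_direction_concordance) {
    ok <- ok & !is.na(sec$direction) & sec$direction == cand$direction
  }
  ok[is.na(ok)] <- FALSE

  out <- data.frame(region_id = cand$region_id, chrom = cand$chrom,
                    start = cand$start, end = cand$end,
                    event_type = cand$event_type,
                    primary_p = cand$p_value, primary_or = cand$odds_ratio,
                    direction = cand$direction,
                    batch1_p = b1$p_value, batch1_or = b1$odds_ratio,
                    batch2_p = b2$p_value, batch2_or = b2$odds_ratio,
                    secondary_region_id = sec$region_id,
                    secondary_p = sec$p_value,
                    secondary_or = sec$odds_ratio,
                    stringsAsFactors = FALSE)[ok, , drop = FALSE]
  out <- out[order(out$primary_p, out$region_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pipeline parameters
#'
#' @param min_overlap Reciprocal-overlap threshold (strict) for merging.
#' @param min_support Minimum distinct supporting callers for a primary
#'   consensus CNV.
#' @param repeat_max_frac Repeat-coverage fraction at which a region is
#'   removed.
#' @param cnvnator A [cnvnator_filter_params()].
#' @param selection A [selection_params()].
#' @param p_burden Significance threshold of the burden summary.
#' @return A `pipeline_params` list.
#' @export
pipeline_params <- function(min_overlap = 0.5, min_support = 2L,
                            repeat_max_frac = 0.5,
                            cnvnator = cnvnator_filter_params(),
                            selection = selection_params(),
                            p_burden = 1e-5) {
  structure(list(min_overlap = min_overlap, min_support = min_support,
                 repeat_max_frac = repeat_max_frac, cnvnator = cnvnator,
                 selection = selection, p_burden = p_burden),
            class = "pipeline_params")
}

#' Run the whole case-control CNV analysis in memory
#'
#' filter -> per-sample merge -> breakpoint segmentation -> repeat filter ->
#' copy states -> association (whole primary cohort and per batch) ->
#' CNVnator-only validation branch -> multi-cohort selection -> burden
#' summary.
#'
#' @param primary_calls All callers' calls for the primary cohort.
#' @param secondary_calls CNVnator calls for the validation cohort.
#' @param sheet Sample sheet for both cohorts.
#' @param repeats Repeat-track data frame (`chrom`, `start`, `end`).
#' @param params A [pipeline_params()].
#' @return List with filtered calls, consensus sets, atomic regions (before
#'   and after the repeat filter), copy-state matrices, the four
#'   association-result tables, `selected` loci, and the `burden` summary.
#' @export
run_cohort_analysis <- function(primary_calls, secondary_calls, sheet,
                                repeats, params = pipeline_params()) {
  sheet <- validate_sample_sheet(sheet)
  prim_samples <- sheet$sample_id[sheet$cohort == "PRIMARY"]
  sec_samples <- sheet$sample_id[sheet$cohort == "SECONDARY"]

  filtered_primary <- filter_calls(primary_calls, params$cnvnator)
  consensus_primary <- merge_calls(filtered_primary, params$min_overlap,
                                   params$min_support)
  regions_primary_all <- build_atomic_regions(consensus_primary)
  regions_primary <- filter_regions_by_repeats(regions_primary_all, repeats,
                                               params$repeat_max_frac)
  csm_primary <- assign_copy_states(regions_primary, consensus_primary,
                                    prim_samples)
  results_primary <- test_all_regions(csm_primary, sheet)
  ctrl_p <- sheet$sample_id[sheet$cohort == "PRIMARY" &
                              sheet$group == "CONTROL"]
  batch_samples <- function(batch) {
    c(sheet$sample_id[sheet$cohort == "PRIMARY" & sheet$group == "CASE" &
                        sheet$batch == batch], ctrl_p)
  }
  results_batch1 <- test_all_regions(csm_primary, sheet,
                                     samples = batch_samples("batch1"))
  results_batch2 <- test_all_regions(csm_primary, sheet,
                                     samples = batch_samples("batch2"))

  filtered_secondary <- filter_calls(secondary_calls, params$cnvnator)
  consensus_secondary <- calls_as_consensus(filtered_secondary)
  regions_secondary_all <- build_atomic_regions(consensus_secondary)
  regions_secondary <- filter_regions_by_repeats(regions_secondary_all,
                                                 repeats,
                                                 params$repeat_max_frac)
  csm_secondary <- assign_copy_states(regions_secondary,
                                      consensus_secondary, sec_samples)
  results_secondary <- test_all_regions(csm_secondary, sheet)

  selected <- select_loci(results_primary, results_batch1, results_batch2,
                          results_secondary, params$selection)
  burden <- global_burden_summary(results_primary, params$p_burden)

  list(params = params, filtered_primary = filtered_primary,
       consensus_primary = consensus_primary,
       regions_primary_all = regions_primary_all,
       regions_primary = regions_primary, csm_primary = csm_primary,
       results_primary = results_primary, results_batch1 = results_batch1,
       results_batch2 = results_batch2,
       filtered_secondary = filtered_secondary,
       consensus_secondary = consensus_secondary,
       regions_secondary_all = regions_secondary_all,
       regions_secondary = regions_secondary,
       csm_secondary = csm_secondary,
       results_secondary = results_secondary, selected = selected,
       burden = burden)
}

#' Run the pipeline from an on-disk fixture
#'
#' Reads the file tree written by [write_fixture()] — `samples.tsv`,
#' `repeats.bed`, `calls_<caller>.tsv` for the primary cohort and
#' `secondary/<sample>.cnvnator.txt` for the validation cohort — runs
#' [run_cohort_analysis()], and (optionally) writes every intermediate and
#' final table plus a parameter log to `outdir`. Rerunning on the same
#' inputs produces byte-identical outputs.
#'
#' @param fixture_dir Input directory.
#' @param outdir Optional output directory for TSV/JSON artifacts.
#' @param params A [pipeline_params()].
#' @return The [run_cohort_analysis()] result list.
#' @export
run_pipeline <- function(fixture_dir, outdir = NULL,
                         params = pipeline_params()) {
  sheet <- read_sample_sheet(file.path(fixture_dir, "samples.tsv"))
  repeats <- read_bed(file.path(fixture_dir, "repeats.bed"))
  call_files <- sort(list.files(fixture_dir, pattern = "^calls_.*\\.tsv$",
                                full.names = TRUE))
  if (!length(call_files)) stop("no calls_<caller>.tsv files in ",
                                fixture_dir)
  primary_calls <- do.call(rbind, lapply(call_files, read_calls_tsv))
  sec_files <- sort(list.files(file.path(fixture_dir, "secondary"),
                               pattern = "\\.cnvnator\\.txt$",
                               full.names = TRUE))
  secondary_calls <- do.call(rbind, c(list(empty_calls()),
    lapply(sec_files, function(f) {
      read_cnvnator(f, sub("\\.cnvnator\\.txt$", "", basename(f)))
    })))

  res <- run_cohort_analysis(primary_calls, secondary_calls, sheet, repeats,
                             params)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, name, drop_members = TRUE) {
      if (drop_members && "members" %in% names(df)) {
        df <- df[setdiff(names(df), "members")]
      }
      utils::write.table(df, file.path(outdir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE, na = "")
    }
    wt(res$consensus_primary, "consensus_primary.tsv")
    wt(res$regions_primary, "regions_primary.tsv")
    wt(res$consensus_secondary, "consensus_secondary.tsv")
    wt(res$regions_secondary, "regions_secondary.tsv")
    write_results_tsv(res$results_primary,
                      file.path(outdir, "results_primary.tsv"))
    write_results_tsv(res$results_batch1,
                      file.path(outdir, "results_batch1.tsv"))
    write_results_tsv(res$results_batch2,
                      file.path(outdir, "results_batch2.tsv"))
    write_results_tsv(res$results_secondary,
                      file.path(outdir, "results_secondary.tsv"))
    wt(res$selected, "selected_loci.tsv")
    log <- list(params = .unclass_deep(params),
                n_primary_calls = nrow(primary_calls),
                n_filtered_primary = nrow(res$filtered_primary),
                n_consensus_primary = nrow(res$consensus_primary),
                n_regions_primary_all = nrow(res$regions_primary_all),
                n_regions_primary = nrow(res$regions_primary),
                n_secondary_calls = nrow(secondary_calls),
                n_regions_secondary = nrow(res$regions_secondary),
                n_selected = nrow(res$selected),
                burden = list(n_loss = length(res$burden$loss_or),
                              n_gain = length(res$burden$gain_or),
                              median_loss = res$burden$median_loss,
                              median_gain = res$burden$median_gain,
                              ranksum_p = res$burden$ranksum_p))
    jsonlite::write_json(log, file.path(outdir, "pipeline_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

.unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), .unclass_deep) else x
}

#' Simulate a study and analyze it end to end
#'
#' Generates truth and noisy callsets for one seed entirely in memory (the
#' five-caller primary cohort, the CNVnator-only validation cohort, and the
#' repeat track) and runs [run_cohort_analysis()].
#'
#' @param config A [simulation_config()].
#' @param params A [pipeline_params()].
#' @return The analysis list, plus `sim` (truth + sheet) and `repeats`.
#' @export
run_simulation_study <- function(config, params = pipeline_params()) {
  sim <- simulate_truth(config)
  repeats <- simulate_repeat_track(config)
  prim <- sim$sheet$sample_id[sim$sheet$cohort == "PRIMARY"]
  sec <- sim$sheet$sample_id[sim$sheet$cohort == "SECONDARY"]
  primary_calls <- do.call(rbind, lapply(seq_along(config$callers),
    function(i) {
      emit_caller_calls(sim, config$callers[[i]],
                        seed = .sub_seed(config$seed, 100L + i),
                        samples = prim)
    }))
  secondary_calls <- emit_caller_calls(sim, .cnvnator_model(config),
                                       seed = .sub_seed(config$seed, 200L),
                                       samples = sec)
  res <- run_cohort_analysis(primary_calls, secondary_calls, sim$sheet,
                             repeats, params)
  res$sim <- sim
  res$repeats <- repeats
  res
}

#' Planted-locus recovery of a selection
#'
#' A planted locus counts as recovered when at least one selected region of
#' its event type has reciprocal overlap > `min_overlap` with it. A
#' selected region is attributed to a planted locus when it lies within
#' `margin` bp of it (breakpoint jitter scatters call boundaries around the
#' true edges, so significant shoulder slivers sit just outside the planted
#' interval); a selected region attributable to no planted locus is a false
#' selection.
#'
#' @param selected Output of [select_loci()].
#' @param planted Planted-locus data frame.
#' @param min_overlap Reciprocal-overlap threshold for recovery.
#' @param margin Attribution window in bp around each planted locus;
#'   typically a few times the simulated `jitter_sd` (0 = strict overlap).
#' @return List `recovered` (named logical per locus) and
#'   `n_false_selected`.
#' @export
planted_locus_recovery <- function(selected, planted, min_overlap = 0.5,
                                   margin = 0) {
  state_of <- c(DEL = "LOSS", DUP = "GAIN")
  recovered <- logical(nrow(planted))
  names(recovered) <- planted$locus_id
  hit_any <- rep(FALSE, nrow(selected))
  for (i in seq_len(nrow(planted))) {
    same <- selected$event_type == state_of[[planted$event_type[i]]] &
      selected$chrom == planted$chrom[i]
    if (!any(same)) next
    ro <- reciprocal_overlap(selected[same, c("chrom", "start", "end")],
                             planted[i, c("chrom", "start", "end")])
    recovered[i] <- any(ro > min_overlap)
    near <- selected$start[same] < planted$end[i] + margin &
      planted$start[i] - margin < selected$end[same]
    hit_any[same] <- hit_any[same] | near
  }
  list(recovered = recovered, n_false_selected = sum(!hit_any))
}
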
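# Call-level quality filtering.
#
# CNVnator calls pass three rules: small e-values (e-val1 and e-val2), a
# clean mapping-quality fraction (q0 < 0.5 and not the -1 sentinel), and for
# deletions a depth ceiling norm_rd < 0.75 * (1 + q0). All inequalities are
# strict. Calls from other callers were produced with their default
# parameters and pass through unchanged.

#' CNVnator filter thresholds
#'
#' @param max_eval Ceiling on e-val1 and e-val2 (strict `<`).
#' @param max_q0 Ceiling on the zero-mapping-quality fraction (strict `<`;
#'   the -1 sentinel is always removed).
#' @param del_rd_factor Deletion depth factor: a deletion call is kept only
#'   if `norm_rd < del_rd_factor * (1 + q0)`. `norm_rd` is in
#'   diploid-normalized units (diploid ~ 1.0), so the default 0.75 admits
#'   heterozygous losses (~0.5) and rejects depth-neutral calls.
#'   Duplications are exempt.
#' @return A `cnvnator_filter_params` list.
#' @export
cnvnator_filter_params <- function(max_eval = 1e-3, max_q0 = 0.5,
                                   del_rd_factor = 0.75) {
  stopifnot(max_eval > 0, max_q0 > 0, max_q0 <= 1, del_rd_factor > 0)
  structure(list(max_eval = max_eval, max_q0 = max_q0,
                 del_rd_factor = del_rd_factor),
            class = "cnvnator_filter_params")
}

#' Filter CNVnator calls on quality
#'
#' Retains a call iff `eval1 < max_eval` and `eval2 < max_eval`, `q0 <
#' max_q0` and `q0 != -1`, and — for deletion calls only — `norm_rd <
#' del_rd_factor * (1 + q0)`. Order is preserved; coordinates and event
#' types are never modified. Idempotent and monotone in the thresholds.
#'
#' @param calls Call data frame with `caller_id == "cnvnator"` and non-null
#'   `eval1`, `eval2`, `q0`, `norm_rd`.
#' @param params A [cnvnator_filter_params()].
#' @return The retained subset of `calls`.
#' @export
filter_cnvnator_calls <- function(calls, params = cnvnator_filter_params()) {
  calls <- validate_calls(calls)
  if (nrow(calls) == 0) return(calls)
  if (any(calls$caller_id != "cnvnator")) {
    stop("filter_cnvnator_calls expects only caller_id 'cnvnator'")
  }
  out <- calls[.cnvnator_keep(calls, params), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.cnvnator_keep <- function(calls, params) {
  for (col in c("eval1", "eval2", "q0", "norm_rd")) {
    bad <- which(is.na(calls[[col]]))
    if (length(bad)) {
      stop(sprintf(
        "CNVnator call %s %s:%d-%d has null %s; quality fields are required",
        calls$sample_id[bad[1]], calls$chrom[bad[1]], calls$start[bad[1]],
        calls$end[bad[1]], col))
    }
  }
  calls$eval1 < params$max_eval & calls$eval2 < params$max_eval &
    calls$q0 < params$max_q0 & calls$q0 != -1 &
    (calls$event_type == "DUP" |
       calls$norm_rd < params$del_rd_factor * (1 + calls$q0))
}

#' Route a mixed-caller call set through the quality filters
#'
#' CNVnator calls go through [filter_cnvnator_calls()]; every other caller's
#' calls are returned unchanged (those callers ran with default parameters,
#' which is their filter). A caller id outside `known_callers` passes
#' through with a warning.
#'
#' @param calls Mixed-caller call data frame.
#' @param params A [cnvnator_filter_params()].
#' @param known_callers Caller ids that do not warrant a warning.
#' @return Filtered call data frame, input order preserved.
#' @export
filter_calls <- function(calls, params = cnvnator_filter_params(),
                         known_callers = c("cnvnator", "gatk_gcnv", "delly2",
                                           "cnmops", "lumpy")) {
  calls <- validate_calls(calls)
  if (nrow(calls) == 0) return(calls)
  unknown <- setdiff(unique(calls$caller_id), known_callers)
  if (length(unknown)) {
    warning("unknown caller_id passed through unfiltered: ",
            paste(unknown, collapse = ", "))
  }
  is_cn <- calls$caller_id == "cnvnator"
  if (!any(is_cn)) return(calls)
  keep_mask <- !is_cn
  keep_mask[is_cn] <- .cnvnator_keep(calls[is_cn, , drop = FALSE], params)
  out <- calls[keep_mask, , drop = FALSE]
  rownames(out) <- NULL
  out
}
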
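# Case-control association over atomic regions.
#
# Each region is tested twice — loss carriers vs rest and gain carriers vs
# rest — with Fisher's exact test on the 2x2 carrier table, and an odds
# ratio with a Wald 95% CI (Haldane-Anscombe 0.5 correction when a cell is
# zero). The global burden summary contrasts the odds-ratio distributions
# of significant losses vs gains with a Wilcoxon rank-sum test.

#' Two-sided Fisher exact p-value for 2x2 tables
#'
#' The conventional minimum-likelihood definition: with margins fixed, the
#' p-value is the sum of hypergeometric probabilities of all tables whose
#' probability is no greater than the observed one (within relative
#' tolerance 1e-7). Vectorized over tables; a single 2x2 matrix is also
#' accepted as the first argument.
#'
#' @param a,b,c,d Cell counts: case carriers, case non-carriers, control
#'   carriers, control non-carriers.
#' @return P-values in (0, 1\].
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L), is.null(b))
    d <- a[2L, 2L]; c <- a[2L, 1L]; b <- a[1L, 2L]; a <- a[1L, 1L]
  }
  if (any(c(a, b, c, d) < 0)) stop("negative cell count")
  if (any(a + b + c + d < 1)) stop("empty table")
  mapply(function(a, b, c, d) {
    r1 <- a + b
    r2 <- c + d
    k <- a + c
    lo <- max(0L, k - r2)
    hi <- min(k, r1)
    probs <- stats::dhyper(lo:hi, r1, r2, k)
    p_obs <- stats::dhyper(a, r1, r2, k)
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }, a, b, c, d)
}

#' Odds ratio with Wald 95% confidence interval
#'
#' `OR = (a * d) / (b * c)`. With `correction = "haldane"`, 0.5 is added to
#' every cell if (and only if) any cell is zero; with `"none"` a zero cell
#' is an error. The CI is `exp(log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c +
#' 1/d))` on the corrected cells. Vectorized.
#'
#' @inheritParams fisher_exact
#' @param correction Zero-cell handling: `"haldane"` (default) or `"none"`.
#' @return Data frame `odds_ratio`, `ci_low`, `ci_high`, `direction`
#'   (`RISK` for OR > 1, `PROTECTIVE` for OR < 1, `NULL` at exactly 1).
#' @export
odds_ratio <- function(a, b = NULL, c = NULL, d = NULL,
                       correction = c("haldane", "none")) {
  correction <- match.arg(correction)
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == 2L), is.null(b))
    d <- a[2L, 2L]; c <- a[2L, 1L]; b <- a[1L, 2L]; a <- a[1L, 1L]
  }
  if (any(c(a, b, c, d) < 0)) stop("negative cell count")
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  if (correction == "none" && any(zero)) {
    stop("zero cell makes the odds ratio undefined; use correction='haldane'")
  }
  adj <- ifelse(zero, 0.5, 0)
  a2 <- a + adj
  b2 <- b + adj
  c2 <- c + adj
  d2 <- d + adj
  or <- (a2 * d2) / (b2 * c2)
  se <- sqrt(1 / a2 + 1 / b2 + 1 / c2 + 1 / d2)
  data.frame(odds_ratio = or, ci_low = exp(log(or) - 1.96 * se),
             ci_high = exp(log(or) + 1.96 * se),
             direction = ifelse(or > 1, "RISK",
                                ifelse(or < 1, "PROTECTIVE", "NULL")),
             stringsAsFactors = FALSE)
}

#' Fisher association of every region, loss and gain separately
#'
#' For each atomic region and each event class (LOSS, GAIN): `a` = case
#' carriers, `b` = case non-carriers, `c`/`d` likewise for controls.
#' Samples whose state at the region is CONFLICT are excluded from that
#' region's denominators. A class with zero carriers overall emits no row.
#' BH q-values are reported across all emitted rows (selection uses raw
#' thresholds).
#'
#' @param csm A `copy_state_matrix` from [assign_copy_states()].
#' @param sheet Sample sheet covering the matrix samples.
#' @param samples Optional subset of sample ids defining the stratum tested
#'   (e.g. one case batch plus the controls); default: all matrix samples.
#' @return Data frame: `region_id`, `chrom`, `start`, `end`, `event_type`
#'   (`LOSS`/`GAIN`), `a`, `b`, `c`, `d`, `p_value`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `direction`, `q_value`.
#' @export
test_all_regions <- function(csm, sheet, samples = NULL) {
  stopifnot(inherits(csm, "copy_state_matrix"))
  sheet <- validate_sample_sheet(sheet)
  if (is.null(samples)) samples <- csm$samples
  missing <- setdiff(samples, csm$samples)
  if (length(missing)) stop("samples not in the copy-state matrix: ",
                            missing[1])
  grp <- sheet$group[match(samples, sheet$sample_id)]
  if (anyNA(grp)) stop("samples missing from the sample sheet: ",
                       samples[which(is.na(grp))[1]])
  cases <- samples[grp == "CASE"]
  ctrls <- samples[grp == "CONTROL"]
  if (!length(cases) || !length(ctrls)) {
    stop("need at least one case and one control in the tested stratum")
  }
  st <- csm$states[, samples, drop = FALSE]
  conflict <- st == 3L
  n_case_eff <- length(cases) -
    rowSums(conflict[, cases, drop = FALSE])
  n_ctrl_eff <- length(ctrls) -
    rowSums(conflict[, ctrls, drop = FALSE])

  one_class <- function(code, label) {
    carrier <- st == code
    a <- rowSums(carrier[, cases, drop = FALSE])
    cc <- rowSums(carrier[, ctrls, drop = FALSE])
    keep <- which(a + cc > 0)
    if (!length(keep)) return(NULL)
    b <- n_case_eff[keep] - a[keep]
    d <- n_ctrl_eff[keep] - cc[keep]
    tab <- data.frame(idx = keep, a = a[keep], b = b, c = cc[keep], d = d)
    # identical tables recur across regions; test each distinct table once
    key <- paste(tab$a, tab$b, tab$c, tab$d)
    u <- !duplicated(key)
    p_u <- fisher_exact(tab$a[u], tab$b[u], tab$c[u], tab$d[u])
    or_u <- odds_ratio(tab$a[u], tab$b[u], tab$c[u], tab$d[u])
    m <- match(key, key[u])
    cbind(data.frame(region_id = csm$regions$region_id[tab$idx],
                     chrom = csm$regions$chrom[tab$idx],
                     start = csm$regions$start[tab$idx],
                     end = csm$regions$end[tab$idx],
                     event_type = label, a = tab$a, b = tab$b, c = tab$c,
                     d = tab$d, p_value = p_u[m],
                     stringsAsFactors = FALSE),
          or_u[m, , drop = FALSE])
  }
  out <- rbind(one_class(1L, "LOSS"), one_class(2L, "GAIN"))
  if (is.null(out)) {
    out <- data.frame(region_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      event_type = character(0), a = integer(0),
                      b = integer(0), c = integer(0), d = integer(0),
                      p_value = numeric(0), odds_ratio = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      direction = character(0), stringsAsFactors = FALSE)
  }
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$chrom, out$start, out$event_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Global gain/loss burden summary
#'
#' Restricts the association results to `p < p_threshold`, collects the
#' odds ratios of significant losses and gains, and compares the two
#' distributions on the log scale with a two-sided Wilcoxon rank-sum test
#' (exact when both groups have at most 10 untied values, otherwise the
#' normal approximation with tie correction). If either class is empty it
#' is reported as such and the rank-sum test is skipped (`NA`).
#'
#' @param results Output of [test_all_regions()].
#' @param p_threshold Significance threshold on the raw Fisher p.
#' @return A `burden_summary` list: `loss_or`, `gain_or`, `median_loss`,
#'   `median_gain`, `ranksum_p`, `p_threshold`.
#' @export
global_burden_summary <- function(results, p_threshold = 1e-5) {
  sig <- results[results$p_value < p_threshold, , drop = FALSE]
  loss_or <- sig$odds_ratio[sig$event_type == "LOSS"]
  gain_or <- sig$odds_ratio[sig$event_type == "GAIN"]
  ranksum_p <- NA_real_
  if (length(loss_or) && length(gain_or)) {
    x <- log(loss_or)
    y <- log(gain_or)
    exact <- length(x) <= 10 && length(y) <= 10 &&
      !any(duplicated(c(x, y)))
    ranksum_p <- stats::wilcox.test(x, y, exact = exact,
                                    correct = FALSE)$p.value
  }
  structure(list(loss_or = loss_or, gain_or = gain_or,
                 median_loss = if (length(loss_or)) stats::median(loss_or)
                 else NA_real_,
                 median_gain = if (length(gain_or)) stats::median(gain_or)
                 else NA_real_,
                 ranksum_p = ranksum_p, p_threshold = p_threshold),
            class = "burden_summary")
}

#' @export
print.burden_summary <- function(x, ...) {
  cat(sprintf("burden summary at p < %g\n", x$p_threshold))
  cat(sprintf("  significant losses: %d (median OR %.3f)\n",
              length(x$loss_or), x$median_loss))
  cat(sprintf("  significant gains:  %d (median OR %.3f)\n",
              length(x$gain_or), x$median_gain))
  cat(sprintf("  rank-sum p (log OR, loss vs gain): %s\n",
              format(x$ranksum_p, digits = 4)))
  invisible(x)
}
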
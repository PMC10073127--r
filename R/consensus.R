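# Consensus merging and breakpoint segmentation.
#
# Within each (sample, event type), calls whose reciprocal overlap exceeds
# the threshold are linked; connected components become consensus CNVs whose
# interval is the union span and whose support counts distinct callers.
# Pooling all samples' consensus endpoints per chromosome and cutting at
# every boundary yields atomic regions — the largest intervals on which
# every sample's copy state is constant — which are then screened against
# the repeat track and turned into a regions x samples copy-state matrix.

#' Reciprocal overlap of two interval sets
#'
#' `min(ov / len(a), ov / len(b))` where `ov` is the shared length; 0 when
#' the intervals are disjoint or on different chromosomes. Vectorized over
#' rows; the shorter argument is recycled.
#'
#' @param a,b Data frames (or one-row lists) with `chrom`, `start`, `end`.
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
reciprocal_overlap <- function(a, b) {
  a <- as.data.frame(a)
  b <- as.data.frame(b)
  n <- max(nrow(a), nrow(b))
  ai <- rep_len(seq_len(nrow(a)), n)
  bi <- rep_len(seq_len(nrow(b)), n)
  ov <- pmin(a$end[ai], b$end[bi]) - pmax(a$start[ai], b$start[bi])
  ov <- pmax(ov, 0)
  ov[a$chrom[ai] != b$chrom[bi]] <- 0
  pmin(ov / (a$end[ai] - a$start[ai]), ov / (b$end[bi] - b$start[bi]))
}

# Core merger over an arbitrary call set, grouping by (sample, type, chrom).
.merge_calls_grouped <- function(calls, min_overlap, min_support) {
  n <- nrow(calls)
  if (n == 0) return(.empty_consensus())
  grp <- paste(calls$sample_id, calls$event_type, calls$chrom, sep = "\r")
  gr <- GenomicRanges::GRanges(grp, IRanges::IRanges(calls$start + 1L,
                                                     calls$end))
  hits <- IRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  if (length(q)) {
    ov <- pmin(calls$end[q], calls$end[s]) - pmax(calls$start[q],
                                                  calls$start[s])
    ro <- pmin(ov / (calls$end[q] - calls$start[q]),
               ov / (calls$end[s] - calls$start[s]))
    edge <- ro > min_overlap
    q <- q[edge]
    s <- s[edge]
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(q)) g <- igraph::add_edges(g, rbind(q, s))
  comp <- igraph::components(g)$membership

  ord <- order(comp)
  cs <- comp[ord]
  first <- which(!duplicated(cs))
  last <- c(first[-1] - 1L, n)
  idx_by_comp <- lapply(seq_along(first),
                        function(i) ord[first[i]:last[i]])
  support <- vapply(idx_by_comp, function(ix)
    length(unique(calls$caller_id[ix])), integer(1))
  keep <- support >= min_support
  idx_by_comp <- idx_by_comp[keep]
  support <- support[keep]
  if (!length(idx_by_comp)) return(.empty_consensus())
  one <- vapply(idx_by_comp, `[`, integer(1), 1L)
  out <- data.frame(
    sample_id = calls$sample_id[one],
    event_type = calls$event_type[one],
    chrom = calls$chrom[one],
    start = vapply(idx_by_comp, function(ix) min(calls$start[ix]),
                   integer(1)),
    end = vapply(idx_by_comp, function(ix) max(calls$end[ix]), integer(1)),
    support = support,
    callers = vapply(idx_by_comp, function(ix)
      paste(sort(unique(calls$caller_id[ix])), collapse = ","),
      character(1)),
    n_members = lengths(idx_by_comp),
    stringsAsFactors = FALSE)
  out$members <- idx_by_comp
  out <- out[order(out$sample_id, out$chrom, out$start, out$end,
                   out$event_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_consensus <- function() {
  out <- data.frame(sample_id = character(0), event_type = character(0),
                    chrom = character(0), start = integer(0),
                    end = integer(0), support = integer(0),
                    callers = character(0), n_members = integer(0),
                    stringsAsFactors = FALSE)
  out$members <- list()
  out
}

#' Merge one sample's multi-caller calls into consensus CNVs
#'
#' Within each event type, calls are linked when their reciprocal overlap
#' strictly exceeds `min_overlap`; connected components (so merging chains
#' transitively) become consensus CNVs spanning the union of their members.
#' Components supported by fewer than `min_support` distinct callers are
#' discarded. The result does not depend on input order.
#'
#' @param calls Call data frame for a single sample.
#' @param min_overlap Reciprocal-overlap threshold (strict), in (0, 1\].
#' @param min_support Minimum number of distinct supporting callers.
#' @return Consensus data frame: `sample_id`, `event_type`, `chrom`,
#'   `start`, `end` (union span), `support`, `callers`, `n_members`, and a
#'   `members` list column of row indices into `calls`.
#' @export
merge_sample_calls <- function(calls, min_overlap = 0.5, min_support = 2L) {
  calls <- validate_calls(calls)
  stopifnot(min_overlap > 0, min_overlap <= 1, min_support >= 1)
  if (length(unique(calls$sample_id)) > 1) {
    stop("merge_sample_calls expects calls from a single sample; got ",
         length(unique(calls$sample_id)))
  }
  .merge_calls_grouped(calls, min_overlap, min_support)
}

#' Merge every sample's calls in one pass
#'
#' Same rule as [merge_sample_calls()], applied per (sample, event type)
#' across a whole cohort's call set in a single overlap query.
#'
#' @inheritParams merge_sample_calls
#' @return Consensus data frame over all samples.
#' @export
merge_calls <- function(calls, min_overlap = 0.5, min_support = 2L) {
  calls <- validate_calls(calls)
  stopifnot(min_overlap > 0, min_overlap <= 1, min_support >= 1)
  .merge_calls_grouped(calls, min_overlap, min_support)
}

#' Treat filtered calls as support-1 consensus CNVs
#'
#' The validation cohort is called with a single caller, so its calls skip
#' merging and enter segmentation directly as consensus CNVs of support 1.
#'
#' @param calls Call data frame (typically filtered CNVnator calls).
#' @return Consensus data frame.
#' @export
calls_as_consensus <- function(calls) {
  calls <- validate_calls(calls)
  out <- data.frame(sample_id = calls$sample_id,
                    event_type = calls$event_type, chrom = calls$chrom,
                    start = calls$start, end = calls$end,
                    support = if (nrow(calls)) 1L else integer(0),
                    callers = calls$caller_id,
                    n_members = if (nrow(calls)) 1L else integer(0),
                    stringsAsFactors = FALSE)
  out$members <- as.list(seq_len(nrow(calls)))
  out <- out[order(out$sample_id, out$chrom, out$start, out$end,
                   out$event_type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cut the genome at every consensus breakpoint
#'
#' Per chromosome, collects all consensus start/end positions, sorts them,
#' and emits each interval between consecutive boundaries that is covered by
#' at least one consensus CNV. The regions are disjoint, sorted, and
#' partition the union footprint of the consensus set exactly.
#'
#' @param consensus Consensus data frame (all samples pooled).
#' @return Data frame `region_id`, `chrom`, `start`, `end`.
#' @export
build_atomic_regions <- function(consensus) {
  if (nrow(consensus) == 0) {
    return(data.frame(region_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- lapply(split(consensus, consensus$chrom), function(cc) {
    b <- sort(unique(c(cc$start, cc$end)))
    cand_s <- b[-length(b)]
    cand_e <- b[-1]
    cov <- IRanges::reduce(IRanges::IRanges(cc$start + 1, cc$end))
    hit <- IRanges::countOverlaps(IRanges::IRanges(cand_s + 1, cand_e),
                                  cov) > 0
    data.frame(chrom = cc$chrom[1], start = cand_s[hit], end = cand_e[hit],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  data.frame(region_id = sprintf("%s:%d-%d", out$chrom, out$start, out$end),
             chrom = out$chrom, start = out$start, end = out$end,
             stringsAsFactors = FALSE)
}

#' Drop regions falling mostly in repeat tracks
#'
#' A region is removed when the fraction of its length covered by the
#' (internally merged) centromere/telomere/segmental-duplication track is
#' `>= max_frac`.
#'
#' @param regions Atomic-region data frame.
#' @param repeat_track Data frame `chrom`, `start`, `end`; intervals may
#'   overlap each other.
#' @param max_frac Removal threshold on covered fraction (default 0.5).
#' @return The retained regions.
#' @export
filter_regions_by_repeats <- function(regions, repeat_track,
                                      max_frac = 0.5) {
  repeat_track <- repeat_track[repeat_track$chrom %in% regions$chrom, ,
                               drop = FALSE]
  if (nrow(regions) == 0 || nrow(repeat_track) == 0) return(regions)
  reg_gr <- .as_gr(regions$chrom, regions$start, regions$end)
  rep_gr <- GenomicRanges::reduce(.as_gr(repeat_track$chrom,
                                         repeat_track$start,
                                         repeat_track$end))
  hits <- GenomicRanges::findOverlaps(reg_gr, rep_gr)
  covered <- numeric(nrow(regions))
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    ov <- pmin(regions$end[q], GenomicRanges::end(rep_gr)[s]) -
      pmax(regions$start[q], GenomicRanges::start(rep_gr)[s] - 1)
    agg <- tapply(ov, q, sum)
    covered[as.integer(names(agg))] <- agg
  }
  frac <- covered / (regions$end - regions$start)
  out <- regions[frac < max_frac, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample copy states over atomic regions
#'
#' A sample is `LOSS` at a region when one of its deletion consensus CNVs
#' covers it, `GAIN` for a duplication, `CONFLICT` when both event types
#' cover it (such cells are excluded from association denominators), and
#' `NEUTRAL` otherwise. Regions must come from [build_atomic_regions()] on
#' the same consensus set, so coverage is all-or-none; a partially covering
#' consensus interval raises a consistency error.
#'
#' @param regions Atomic-region data frame.
#' @param consensus Consensus data frame (all samples pooled).
#' @param samples Character vector defining the sample (column) order.
#' @return A `copy_state_matrix`: list with `regions`, `samples`, and an
#'   integer `states` matrix (0 = NEUTRAL, 1 = LOSS, 2 = GAIN,
#'   3 = CONFLICT).
#' @export
assign_copy_states <- function(regions, consensus, samples) {
  nR <- nrow(regions)
  nS <- length(samples)
  states <- matrix(0L, nR, nS, dimnames = list(regions$region_id, samples))
  cons <- consensus[consensus$sample_id %in% samples, , drop = FALSE]
  if (nR > 0 && nrow(cons) > 0) {
    reg_gr <- .as_gr(regions$chrom, regions$start, regions$end)
    con_gr <- .as_gr(cons$chrom, cons$start, cons$end)
    hits <- suppressWarnings(GenomicRanges::findOverlaps(reg_gr, con_gr))
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    if (length(q)) {
      full <- cons$start[s] <= regions$start[q] &
        cons$end[s] >= regions$end[q]
      if (!all(full)) {
        b <- which(!full)[1]
        stop(sprintf(
          paste0("consensus CNV %s:%s-%s (%s) partially overlaps region %s;",
                 " regions were not derived from this consensus set"),
          cons$chrom[s[b]], format(cons$start[s[b]], scientific = FALSE),
          format(cons$end[s[b]], scientific = FALSE),
          cons$sample_id[s[b]], regions$region_id[q[b]]))
      }
      col <- match(cons$sample_id[s], samples)
      bit <- ifelse(cons$event_type[s] == "DEL", 1L, 2L)
      # accumulate LOSS and GAIN bits; 1|2 -> 3 = CONFLICT
      loss_cells <- unique(cbind(q, col)[bit == 1L, , drop = FALSE])
      gain_cells <- unique(cbind(q, col)[bit == 2L, , drop = FALSE])
      loss <- matrix(FALSE, nR, nS)
      gain <- matrix(FALSE, nR, nS)
      loss[loss_cells] <- TRUE
      gain[gain_cells] <- TRUE
      states[] <- loss + 2L * gain
    }
  }
  structure(list(regions = regions, samples = samples, states = states),
            class = "copy_state_matrix")
}

COPY_STATES <- c(NEUTRAL = 0L, LOSS = 1L, GAIN = 2L, CONFLICT = 3L)

#' @method as.matrix copy_state_matrix
#' @export
as.matrix.copy_state_matrix <- function(x, ...) {
  m <- names(COPY_STATES)[x$states + 1L]
  matrix(m, nrow(x$states), ncol(x$states), dimnames = dimnames(x$states))
}

#' Copy state of one cell
#'
#' @param csm A `copy_state_matrix`.
#' @param region_id,sample_id Cell coordinates.
#' @return One of `"NEUTRAL"`, `"LOSS"`, `"GAIN"`, `"CONFLICT"`.
#' @export
copy_state <- function(csm, region_id, sample_id) {
  names(COPY_STATES)[csm$states[region_id, sample_id] + 1L]
}

#' @export
print.copy_state_matrix <- function(x, ...) {
  tab <- table(factor(names(COPY_STATES)[x$states + 1L],
                      levels = names(COPY_STATES)))
  cat(sprintf("copy_state_matrix: %d regions x %d samples\n",
              nrow(x$states), ncol(x$states)))
  print(tab)
  invisible(x)
}
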
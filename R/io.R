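# On-disk formats and the coordinate model.
#
# Every interval in the package is 0-based half-open [start, end) on an opaque
# chromosome token. BED is already in that convention; the CNVnator text
# dialect is 1-based fully closed and is shifted exactly once, on read.

CALL_COLUMNS <- c("sample_id", "caller_id", "chrom", "start", "end",
                  "event_type", "norm_rd", "eval1", "eval2", "eval3",
                  "eval4", "q0")
EVENT_TYPES <- c("DEL", "DUP")

#' Empty CNV call table
#'
#' Returns a zero-row data frame with the canonical call columns:
#' `sample_id`, `caller_id`, `chrom`, `start`, `end` (0-based half-open),
#' `event_type` (`"DEL"`/`"DUP"`), and the CNVnator quality fields
#' `norm_rd`, `eval1`..`eval4`, `q0` (NA for callers without them).
#'
#' @return A zero-row call data frame.
#' @export
empty_calls <- function() {
  data.frame(sample_id = character(0), caller_id = character(0),
             chrom = character(0), start = integer(0), end = integer(0),
             event_type = character(0), norm_rd = numeric(0),
             eval1 = numeric(0), eval2 = numeric(0), eval3 = numeric(0),
             eval4 = numeric(0), q0 = numeric(0),
             stringsAsFactors = FALSE)
}

# internal: half-open data-frame intervals -> GRanges (1-based closed)
.as_gr <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
}

.check_intervals <- function(start, end, what = "interval") {
  bad <- which(!(is.finite(start) & is.finite(end) & start >= 0 & start < end))
  if (length(bad)) {
    stop(sprintf("invalid %s at row %d: need 0 <= start < end (got [%s, %s))",
                 what, bad[1], format(start[bad[1]]), format(end[bad[1]])))
  }
  invisible(TRUE)
}

#' Validate a CNV call table
#'
#' Checks column presence, coordinate sanity (0 <= start < end), event types
#' in `DEL`/`DUP`, `q0` equal to the -1 sentinel or in \[0, 1\], and
#' non-negative `norm_rd` where present.
#'
#' @param calls A call data frame (see [empty_calls()]).
#' @return `calls`, invisibly, with columns in canonical order.
#' @export
validate_calls <- function(calls) {
  missing <- setdiff(CALL_COLUMNS, names(calls))
  if (length(missing)) {
    stop("call table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(calls) == 0) return(invisible(calls[CALL_COLUMNS]))
  bad_type <- which(!calls$event_type %in% EVENT_TYPES)
  if (length(bad_type)) {
    stop(sprintf("unsupported event_type '%s' at row %d (only DEL/DUP)",
                 calls$event_type[bad_type[1]], bad_type[1]))
  }
  .check_intervals(calls$start, calls$end, "call interval")
  q0 <- calls$q0
  bad_q0 <- which(!is.na(q0) & !(q0 == -1 | (q0 >= 0 & q0 <= 1)))
  if (length(bad_q0)) {
    stop(sprintf("q0 must be -1 or in [0,1]; row %d has %s",
                 bad_q0[1], format(q0[bad_q0[1]])))
  }
  bad_rd <- which(!is.na(calls$norm_rd) & calls$norm_rd < 0)
  if (length(bad_rd)) {
    stop(sprintf("norm_rd must be >= 0; row %d has %s",
                 bad_rd[1], format(calls$norm_rd[bad_rd[1]])))
  }
  invisible(calls[CALL_COLUMNS])
}

#' Read a BED track of genomic intervals
#'
#' Reads 3+ column BED (0-based half-open). `track`, `browser` and `#` lines
#' are skipped; extra columns are ignored.
#'
#' @param path Path to a BED file.
#' @return Data frame with columns `chrom`, `start`, `end`, one row per data
#'   line in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_data <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(is_data)
  if (!length(idx)) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(trimws(lines[idx]), "[ \t]+")
  short <- which(lengths(parts) < 3)
  if (length(short)) {
    stop(sprintf("BED parse error at line %d: fewer than 3 columns",
                 idx[short[1]]))
  }
  chrom <- vapply(parts, `[`, character(1), 1L)
  start_chr <- vapply(parts, `[`, character(1), 2L)
  end_chr <- vapply(parts, `[`, character(1), 3L)
  start <- suppressWarnings(as.integer(start_chr))
  end <- suppressWarnings(as.integer(end_chr))
  bad <- which(is.na(start) | is.na(end) | start_chr != as.character(start) |
                 end_chr != as.character(end))
  if (length(bad)) {
    stop(sprintf("BED parse error at line %d: non-integer coordinate",
                 idx[bad[1]]))
  }
  bad <- which(!(start >= 0 & start < end))
  if (length(bad)) {
    stop(sprintf("BED parse error at line %d: need 0 <= start < end",
                 idx[bad[1]]))
  }
  data.frame(chrom = chrom, start = start, end = end, stringsAsFactors = FALSE)
}

#' Write a BED track
#'
#' @param intervals Data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  .check_intervals(intervals$start, intervals$end, "BED interval")
  utils::write.table(intervals[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read CNVnator native text output
#'
#' Parses the canonical CNVnator call dialect: whitespace-delimited columns
#' `type` (`deletion`/`duplication`), `coordinates` (`chrom:start-end`,
#' 1-based fully closed), `length`, `normalized_RD`, `e-val1`..`e-val4`, `q0`.
#' Coordinates are converted to the package's 0-based half-open convention
#' (start - 1, end); `q0 = -1` is retained as the undefined sentinel.
#'
#' @param path Path to a CNVnator output file.
#' @param sample_id Sample the file belongs to.
#' @return A call data frame with `caller_id = "cnvnator"`.
#' @export
read_cnvnator <- function(path, sample_id) {
  if (!file.exists(path)) stop("CNVnator file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  idx <- which(nzchar(trimws(lines)) & !grepl("^#", lines))
  if (!length(idx)) {
    out <- empty_calls()
    return(out)
  }
  parts <- strsplit(trimws(lines[idx]), "[ \t]+")
  short <- which(lengths(parts) < 9)
  if (length(short)) {
    stop(sprintf("CNVnator parse error at line %d: expected 9 columns",
                 idx[short[1]]))
  }
  type_tok <- vapply(parts, `[`, character(1), 1L)
  event_type <- c(deletion = "DEL", duplication = "DUP")[type_tok]
  bad <- which(is.na(event_type))
  if (length(bad)) {
    stop(sprintf("CNVnator parse error at line %d: unknown type '%s'",
                 idx[bad[1]], type_tok[bad[1]]))
  }
  coord <- vapply(parts, `[`, character(1), 2L)
  m <- regmatches(coord, regexec("^([^:]+):([0-9]+)-([0-9]+)$", coord))
  bad <- which(lengths(m) != 4)
  if (length(bad)) {
    stop(sprintf("CNVnator parse error at line %d: bad coordinates '%s'",
                 idx[bad[1]], coord[bad[1]]))
  }
  chrom <- vapply(m, `[`, character(1), 2L)
  start1 <- as.integer(vapply(m, `[`, character(1), 3L))
  end1 <- as.integer(vapply(m, `[`, character(1), 4L))
  num <- function(j) as.numeric(vapply(parts, `[`, character(1), j))
  calls <- data.frame(sample_id = sample_id, caller_id = "cnvnator",
                      chrom = chrom, start = start1 - 1L, end = end1,
                      event_type = unname(event_type), norm_rd = num(4L),
                      eval1 = num(5L), eval2 = num(6L), eval3 = num(7L),
                      eval4 = num(8L), q0 = num(9L),
                      stringsAsFactors = FALSE)
  validate_calls(calls)
  calls
}

#' Write calls in the CNVnator native dialect
#'
#' Inverse of [read_cnvnator()]: coordinates are shifted back to 1-based
#' fully closed. Used by the simulator to emit validation-cohort files.
#'
#' @param calls Call data frame (single caller, typically `cnvnator`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cnvnator <- function(calls, path) {
  calls <- validate_calls(calls)
  type_tok <- c(DEL = "deletion", DUP = "duplication")[calls$event_type]
  lines <- sprintf("%s\t%s:%d-%d\t%d\t%s\t%s\t%s\t%s\t%s\t%s",
                   type_tok, calls$chrom, calls$start + 1L, calls$end,
                   calls$end - calls$start,
                   sprintf("%.17g", calls$norm_rd),
                   sprintf("%.17g", calls$eval1), sprintf("%.17g", calls$eval2),
                   sprintf("%.17g", calls$eval3), sprintf("%.17g", calls$eval4),
                   sprintf("%.17g", calls$q0))
  writeLines(lines, path)
  invisible(path)
}

# numeric columns are written with %.17g so read(write(x)) is bit-identical
.fmt_num <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))

#' Read/write the generic caller call TSV
#'
#' The interchange dialect for all callers: a header row with the canonical
#' call columns, coordinates 0-based half-open, empty string for null quality
#' fields. `read_calls_tsv(write_calls_tsv(x))` is the identity.
#'
#' @param path File path.
#' @return `read_calls_tsv`: a validated call data frame.
#' @export
read_calls_tsv <- function(path) {
  if (!file.exists(path)) stop("calls TSV not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  missing <- setdiff(CALL_COLUMNS, header)
  if (length(missing)) {
    stop("calls TSV is missing columns: ", paste(missing, collapse = ", "))
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE, na.strings = "",
                          stringsAsFactors = FALSE,
                          colClasses = c(sample_id = "character",
                                         caller_id = "character",
                                         chrom = "character",
                                         start = "integer", end = "integer",
                                         event_type = "character",
                                         norm_rd = "numeric",
                                         eval1 = "numeric", eval2 = "numeric",
                                         eval3 = "numeric", eval4 = "numeric",
                                         q0 = "numeric"))
  df <- df[CALL_COLUMNS]
  validate_calls(df)
  df
}

#' @rdname read_calls_tsv
#' @param calls Call data frame to write.
#' @return `write_calls_tsv`: `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  calls <- validate_calls(calls)
  if (nrow(calls) == 0) calls <- empty_calls()
  out <- calls
  for (col in c("norm_rd", "eval1", "eval2", "eval3", "eval4", "q0")) {
    out[[col]] <- .fmt_num(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' TSV with header `sample_id`, `group` (`CASE`/`CONTROL`), `cohort`
#' (`PRIMARY`/`SECONDARY`), `batch` (free token, e.g. `batch1`/`batch2`/`hc`).
#' Sample ids must be unique, so no sample can sit in two cohorts.
#'
#' @param path File path.
#' @return A validated sample-sheet data frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  validate_sample_sheet(df)
}

#' @rdname read_sample_sheet
#' @param sheet Sample-sheet data frame.
#' @return `validate_sample_sheet`: the sheet, columns in canonical order.
#' @export
validate_sample_sheet <- function(sheet) {
  cols <- c("sample_id", "group", "cohort", "batch")
  missing <- setdiff(cols, names(sheet))
  if (length(missing)) {
    stop("sample sheet is missing columns: ", paste(missing, collapse = ", "))
  }
  dup <- sheet$sample_id[duplicated(sheet$sample_id)]
  if (length(dup)) stop("duplicated sample_id: ", dup[1])
  bad <- setdiff(unique(sheet$group), c("CASE", "CONTROL"))
  if (length(bad)) stop("unknown group token: ", bad[1])
  bad <- setdiff(unique(sheet$cohort), c("PRIMARY", "SECONDARY"))
  if (length(bad)) stop("unknown cohort token: ", bad[1])
  sheet[cols]
}

#' @rdname read_sample_sheet
#' @return `write_sample_sheet`: `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  sheet <- validate_sample_sheet(sheet)
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

RESULT_COLUMNS <- c("chrom", "start", "end", "event_type", "a", "b", "c", "d",
                    "p_value", "odds_ratio", "ci_low", "ci_high", "direction",
                    "region_id", "q_value")

#' Write an association results table
#'
#' Stable column order: region coordinates, event type, 2x2 cells `a`
#' (case carriers), `b` (case non-carriers), `c` (control carriers), `d`
#' (control non-carriers), Fisher p, odds ratio with 95% CI, risk
#' direction, then `region_id` and BH `q_value`.
#'
#' @param results Association results data frame (see [test_all_regions()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  missing <- setdiff(RESULT_COLUMNS, names(results))
  if (length(missing)) {
    stop("results table is missing columns: ", paste(missing, collapse = ", "))
  }
  out <- results[RESULT_COLUMNS]
  for (col in c("p_value", "odds_ratio", "ci_low", "ci_high", "q_value")) {
    out[[col]] <- .fmt_num(out[[col]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_results_tsv
#' @return `read_results_tsv`: the results data frame.
#' @export
read_results_tsv <- function(path) {
  if (!file.exists(path)) stop("results TSV not found: ", path)
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = "",
                    stringsAsFactors = FALSE)
}
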
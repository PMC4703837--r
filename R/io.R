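#' @importFrom GenomicRanges GRanges reduce findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

# All coordinates in the package are 0-based half-open (BED convention).
# GRanges is 1-based closed; these two helpers are the only place the
# offset changes.

#' Convert a peak data.frame to GRanges
#'
#' @param peaks data.frame with `scaffold`, `start`, `end` (0-based
#'   half-open) and optionally `strand`.
#' @return A [GenomicRanges::GRanges] (1-based closed).
#' @export
peaks_to_granges <- function(peaks) {
  strand <- if ("strand" %in% names(peaks)) {
    ifelse(peaks$strand %in% c("+", "-"), peaks$strand, "*")
  } else "*"
  GenomicRanges::GRanges(
    seqnames = peaks$scaffold,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    strand = strand
  )
}

#' Convert a GRanges back to a 0-based half-open peak data.frame
#'
#' @param gr A [GenomicRanges::GRanges].
#' @return data.frame with `scaffold`, `start`, `end`.
#' @export
granges_to_peaks <- function(gr) {
  data.frame(
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

validate_intervals <- function(df, source = "input", line_offset = 0L) {
  bad <- which(is.na(df$start) | is.na(df$end) | df$start < 0 |
                 df$end <= df$start | is.na(df$scaffold) | df$scaffold == "")
  if (length(bad)) {
    stop(sprintf(
      "%s: rejected record at line %d (start=%s, end=%s): need 0 <= start < end and non-empty scaffold",
      source, bad[1] + line_offset,
      as.character(df$start[bad[1]]), as.character(df$end[bad[1]])))
  }
  invisible(df)
}

#' Read peaks from BED or a tabular counts file
#'
#' BED input needs at least 3 columns (scaffold, start, end; 0-based
#' half-open); columns 4/5/6 are taken as name, score, strand when present.
#' Tabular input (`format = "counts"`) must have a header with `scaffold`,
#' `start`, `end` plus any number of count/score columns, which are kept.
#'
#' @param path File path.
#' @param format `"bed"` or `"counts"`.
#' @param strict Logical; if `TRUE` (default) any malformed line is an
#'   error naming its line number, otherwise bad lines are dropped with a
#'   message reporting how many were skipped.
#' @return Coordinate-sorted data.frame of peaks.
#' @export
read_peaks <- function(path, format = c("bed", "counts"), strict = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "bed") {
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    bad <- which(keep & nf < 3)
    if (length(bad)) {
      if (strict) stop("malformed line ", bad[1], " in ", path,
                       ": fewer than 3 tab-separated fields")
      message("read_peaks: skipped ", length(bad), " malformed line(s)")
      keep[bad] <- FALSE
    }
    idx <- which(keep)
    if (!length(idx)) {
      return(data.frame(scaffold = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE))
    }
    fl <- fields[idx]
    df <- data.frame(
      scaffold = vapply(fl, `[`, "", 1L),
      start = suppressWarnings(as.integer(vapply(fl, `[`, "", 2L))),
      end = suppressWarnings(as.integer(vapply(fl, `[`, "", 3L))),
      stringsAsFactors = FALSE
    )
    if (any(nf[idx] >= 4)) df$name <- vapply(fl, function(x) if (length(x) >= 4) x[4] else NA_character_, "")
    if (any(nf[idx] >= 6)) df$strand <- vapply(fl, function(x) if (length(x) >= 6) x[6] else "*", "")
    bad2 <- which(is.na(df$start) | is.na(df$end) | df$start < 0 | df$end <= df$start)
    if (length(bad2)) {
      if (strict) {
        stop("malformed line ", idx[bad2[1]], " in ", path,
             ": need integer 0 <= start < end")
      }
      message("read_peaks: skipped ", length(bad2), " invalid record(s)")
      df <- df[-bad2, , drop = FALSE]
    }
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("scaffold", "start", "end")
    if (!all(need %in% names(df))) {
      stop("counts table ", path, " must have header columns scaffold/start/end")
    }
    validate_intervals(df, source = path, line_offset = 1L)
  }
  df[order(df$scaffold, df$start, df$end), , drop = FALSE]
}

#' Write peaks to BED or tabular format
#'
#' Inverse of [read_peaks()]: coordinates and any extra columns
#' round-trip exactly.
#'
#' @param peaks Peak data.frame (0-based half-open).
#' @param path Output path.
#' @param format `"bed"` (first 3-6 columns, no header) or `"counts"`
#'   (all columns, tab-separated with header).
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path, format = c("bed", "counts")) {
  format <- match.arg(format)
  validate_intervals(peaks, source = "write_peaks")
  if (format == "bed") {
    cols <- intersect(c("scaffold", "start", "end", "name", "score", "strand"),
                      names(peaks))
    utils::write.table(peaks[, cols, drop = FALSE], path, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.table(peaks, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  invisible(path)
}

#' Union of several peak sets
#'
#' Overlapping and bookended (zero-gap) intervals are coalesced, matching
#' peak-caller merge semantics; output is sorted and non-overlapping.
#' Merged replicate/stage peak sets avoid bias caused by peak calling in
#' any single sample.
#'
#' @param sets List of peak data.frames.
#' @return Sorted, non-overlapping peak data.frame (columns scaffold,
#'   start, end). Empty input gives an empty frame.
#' @export
merge_peak_sets <- function(sets) {
  sets <- Filter(function(s) !is.null(s) && nrow(s) > 0, sets)
  if (!length(sets)) {
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  }
  all <- do.call(rbind, lapply(sets, function(s) s[c("scaffold", "start", "end")]))
  gr <- GenomicRanges::reduce(peaks_to_granges(all))
  out <- granges_to_peaks(gr)
  out[order(out$scaffold, out$start), , drop = FALSE]
}

#' Restrict intervals to a scaffold whitelist
#'
#' Only the chromosome-sized scaffolds are analysed; everything else is
#' dropped. Order of retained rows is preserved.
#'
#' @param items data.frame with a `scaffold` column.
#' @param whitelist Character vector of allowed scaffolds.
#' @return Filtered data.frame.
#' @export
restrict_scaffolds <- function(items, whitelist) {
  if (!length(whitelist)) stop("scaffold whitelist is empty")
  items[items$scaffold %in% whitelist, , drop = FALSE]
}

#' Read a TSS table
#'
#' Tab-separated with header columns `gene_id`, `scaffold`, `tss`
#' (0-based position), `strand` (+/-). One canonical TSS per gene.
#'
#' @param path File path.
#' @return data.frame of TSS records.
#' @export
read_tss <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("gene_id", "scaffold", "tss", "strand")
  if (!all(need %in% names(df))) {
    stop("TSS table must have columns gene_id/scaffold/tss/strand")
  }
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id in TSS table: one canonical TSS per gene required")
  }
  if (!all(df$strand %in% c("+", "-"))) stop("TSS strand must be + or -")
  df
}

#' Promoter windows around TSSs
#'
#' Symmetric strand-aware windows `[tss - flank, tss + flank)` clipped at 0.
#'
#' @param tss TSS data.frame (see [read_tss()]).
#' @param flank Half-width in bp.
#' @return Peak-style data.frame with `gene_id`, `scaffold`, `start`, `end`.
#' @export
promoter_windows <- function(tss, flank) {
  data.frame(
    gene_id = tss$gene_id,
    scaffold = tss$scaffold,
    start = pmax(0L, as.integer(tss$tss - flank)),
    end = as.integer(tss$tss + flank),
    stringsAsFactors = FALSE
  )
}
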
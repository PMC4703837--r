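#' Reads per kilobase per million (RPKM)
#'
#' @param count Read count(s) in the region.
#' @param length Region length(s) in bp; must be positive.
#' @param library_size Total aligned reads in the sample; must be positive.
#' @return `count / ((length/1000) * (library_size/1e6))`, vectorized.
#' @examples
#' compute_rpkm(10, 1000, 1e6)  # 10
#' @export
compute_rpkm <- function(count, length, library_size) {
  if (any(length <= 0)) stop("region length must be positive")
  if (any(library_size <= 0)) stop("library size must be positive")
  count / ((length / 1000) * (library_size / 1e6))
}

#' Nearest-rank percentile
#'
#' The p-th percentile as the `ceiling(p * n)`-th order statistic — an
#' unambiguous definition with no interpolation dialects.
#'
#' @param x Numeric vector.
#' @param p Percentile in (0, 1].
#' @return The nearest-rank percentile of `x`.
#' @export
nearest_rank_percentile <- function(x, p = 0.95) {
  stopifnot(length(x) >= 1, p > 0, p <= 1)
  sort(x)[ceiling(p * length(x))]
}

#' Sample random background regions
#'
#' Intervals are placed uniformly on whitelisted scaffolds with widths
#' resampled from the observed peak-width distribution. Used to anchor
#' the 95th-percentile background RPKM that relative RPKM is measured
#' against.
#'
#' @param scaffolds data.frame with `scaffold` and `length` columns.
#' @param peak_widths Integer vector of peak widths to resample from.
#' @param n_regions Number of regions (>= 100).
#' @param seed Integer seed.
#' @param whitelist Optional scaffold whitelist; defaults to all given
#'   scaffolds.
#' @return data.frame of background intervals (scaffold, start, end).
#' @export
sample_background <- function(scaffolds, peak_widths, n_regions = 10000L,
                              seed = 1L, whitelist = NULL) {
  if (n_regions < 100) stop("need at least 100 background regions")
  if (!is.null(whitelist)) {
    scaffolds <- scaffolds[scaffolds$scaffold %in% whitelist, , drop = FALSE]
  }
  if (!nrow(scaffolds)) stop("no whitelisted scaffolds to sample from")
  with_seed(seed + 707L, {
    out <- data.frame(scaffold = character(n_regions), start = integer(n_regions),
                      end = integer(n_regions), stringsAsFactors = FALSE)
    for (i in seq_len(n_regions)) {
      placed <- FALSE
      for (attempt in 1:100) {
        w <- sample(peak_widths, 1)
        si <- sample.int(nrow(scaffolds), 1)
        if (scaffolds$length[si] > w) {
          s <- floor(stats::runif(1, 0, scaffolds$length[si] - w))
          out$scaffold[i] <- scaffolds$scaffold[si]
          out$start[i] <- as.integer(s)
          out$end[i] <- as.integer(s + w)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place background region after 100 attempts: ",
                        "all scaffolds shorter than sampled widths")
    }
    out
  })
}

#' Background model from background-region counts
#'
#' Computes per-sample RPKM of the background regions and the
#' nearest-rank 95th percentile each sample's relative RPKM is divided
#' by.
#'
#' @param counts Matrix or data.frame of background read counts
#'   (regions x samples).
#' @param widths Region widths in bp.
#' @param library_size Per-sample library sizes (recycled).
#' @param percentile Percentile of the background distribution
#'   (default 0.95).
#' @return List with `p95` (named per-sample percentile RPKM), `rpkm`,
#'   `n_regions`, `percentile`.
#' @export
background_model <- function(counts, widths, library_size,
                             percentile = 0.95) {
  counts <- as.matrix(counts)
  library_size <- rep(library_size, length.out = ncol(counts))
  rpkm <- sweep(counts / (widths / 1000), 2, library_size / 1e6, "/")
  p95 <- apply(rpkm, 2, nearest_rank_percentile, p = percentile)
  list(p95 = p95, rpkm = rpkm, n_regions = nrow(counts),
       percentile = percentile)
}

#' Relative RPKM
#'
#' Peak RPKM divided by the 95th-percentile RPKM of random background
#' regions of the same sample. The classifier thresholds
#' ("rel. RPKM > 1") operate on this value; it is invariant under
#' uniform scaling of all counts in a sample.
#'
#' @param peak_rpkm Numeric vector of peak RPKMs.
#' @param background_p95 The background percentile RPKM (scalar, > 0).
#' @return `peak_rpkm / background_p95`.
#' @export
relative_rpkm <- function(peak_rpkm, background_p95) {
  if (length(background_p95) != 1 || is.na(background_p95) || background_p95 <= 0) {
    stop("degenerate background: 95th-percentile RPKM must be positive")
  }
  peak_rpkm / background_p95
}

#' Exclude peaks lying in high-input regions
#'
#' A peak is excluded when at least `overlap_fraction` (default 75%) of
#' its length lies within 1-kb input bins holding more than
#' `count_threshold` (default 65) input reads — regions where apparent
#' ChIP enrichment tracks input artefacts.
#'
#' @param peaks Peak data.frame.
#' @param input_track data.frame (scaffold, start, end, count) of input
#'   read counts binned at exactly `bin_size` bp.
#' @param overlap_fraction Minimum flagged-overlap fraction to exclude.
#' @param count_threshold Input reads above which a bin is flagged
#'   (strictly greater than).
#' @param bin_size Required input bin width (default 1000).
#' @return `peaks` with logical `excluded` and character `reason`
#'   columns (existing exclusions are kept; the filter is idempotent).
#' @export
input_exclusion_filter <- function(peaks, input_track,
                                   overlap_fraction = 0.75,
                                   count_threshold = 65,
                                   bin_size = 1000L) {
  if (any(input_track$end - input_track$start != bin_size)) {
    stop("input track must be binned at exactly ", bin_size, " bp")
  }
  if (is.null(peaks$excluded)) {
    peaks$excluded <- FALSE
    peaks$reason <- NA_character_
  }
  flagged <- input_track[input_track$count > count_threshold, , drop = FALSE]
  frac <- numeric(nrow(peaks))
  if (nrow(flagged) && nrow(peaks)) {
    pg <- peaks_to_granges(peaks)
    fg <- peaks_to_granges(flagged)
    hits <- GenomicRanges::findOverlaps(pg, fg)
    if (length(hits)) {
      ov <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(pg)[S4Vectors::queryHits(hits)],
        IRanges::ranges(fg)[S4Vectors::subjectHits(hits)]))
      bp <- tapply(ov, S4Vectors::queryHits(hits), sum)
      frac[as.integer(names(bp))] <- as.numeric(bp)
    }
    frac <- frac / (peaks$end - peaks$start)
  }
  hit <- frac >= overlap_fraction
  newly <- hit & !peaks$excluded
  peaks$excluded <- peaks$excluded | hit
  peaks$reason[newly] <- "high_input"
  peaks
}

#' Exclude peaks not exceeding the random-background signal
#'
#' By default a peak must exceed the 95th-percentile background signal
#' (relative RPKM > 1) to be retained; weaker peaks are excluded. With
#' `literal_mode = TRUE` the opposite direction is applied (peaks
#' exceeding background are excluded) — see the methods vignette for why
#' the default inverts that reading.
#'
#' @param peaks Peak data.frame with a relative-RPKM column.
#' @param column Name of the relative-RPKM column (default
#'   `"rel_rpkm"`).
#' @param literal_mode Apply the exclusion to peaks with relative
#'   RPKM > 1 instead.
#' @return `peaks` with `excluded`/`reason` updated; idempotent.
#' @export
background_signal_filter <- function(peaks, column = "rel_rpkm",
                                     literal_mode = FALSE) {
  if (is.null(peaks[[column]])) stop("missing relative-RPKM column: ", column)
  if (is.null(peaks$excluded)) {
    peaks$excluded <- FALSE
    peaks$reason <- NA_character_
  }
  hit <- if (literal_mode) peaks[[column]] > 1 else peaks[[column]] <= 1
  newly <- hit & !peaks$excluded
  peaks$excluded <- peaks$excluded | hit
  peaks$reason[newly] <- if (literal_mode) "above_background" else "background_level"
  peaks
}

#' Strand-aware signal matrix around TSSs
#'
#' Extracts mean track signal in `bin`-bp bins over `[tss - flank,
#' tss + flank)`, reversing bins for minus-strand genes so that all rows
#' read 5' to 3'. Bases not covered by the track count as 0; windows
#' running off the scaffold edge are padded with `NA`.
#'
#' @param track data.frame (scaffold, start, end, value) signal track.
#' @param tss TSS data.frame (gene_id, scaffold, tss, strand).
#' @param flank Half-window in bp; must be a multiple of `bin`.
#' @param bin Bin width in bp.
#' @param scaffold_lengths Optional named vector of scaffold lengths for
#'   edge padding (default: no right-edge padding).
#' @return genes x bins numeric matrix, row order = input gene order.
#' @export
tss_profile_matrix <- function(track, tss, flank, bin,
                               scaffold_lengths = NULL) {
  if (flank %% bin != 0) stop("flank must be a multiple of bin")
  nb <- 2L * (flank %/% bin)
  n <- nrow(tss)
  out <- matrix(0, n, nb,
                dimnames = list(tss$gene_id,
                                as.character(seq(-flank, flank - bin, by = bin))))
  # window bins as one GRanges: gene g, bin k covers [tss-flank+(k-1)*bin, +bin)
  g_idx <- rep(seq_len(n), each = nb)
  b_idx <- rep(seq_len(nb), n)
  bstart <- tss$tss[g_idx] - flank + (b_idx - 1L) * bin
  bend <- bstart + bin
  valid <- bstart >= 0
  if (!is.null(scaffold_lengths)) {
    lim <- scaffold_lengths[tss$scaffold[g_idx]]
    valid <- valid & (bend <= lim)
  }
  out[cbind(g_idx[!valid], b_idx[!valid])] <- NA
  vg <- which(valid)
  if (length(vg) && nrow(track)) {
    wins <- GenomicRanges::GRanges(tss$scaffold[g_idx[vg]],
                                   IRanges::IRanges(bstart[vg] + 1L, bend[vg]))
    tg <- peaks_to_granges(track)
    hits <- GenomicRanges::findOverlaps(wins, tg)
    if (length(hits)) {
      ov <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(wins)[S4Vectors::queryHits(hits)],
        IRanges::ranges(tg)[S4Vectors::subjectHits(hits)]))
      contrib <- ov * track$value[S4Vectors::subjectHits(hits)]
      acc <- tapply(contrib, S4Vectors::queryHits(hits), sum)
      ids <- vg[as.integer(names(acc))]
      out[cbind(g_idx[ids], b_idx[ids])] <- as.numeric(acc) / bin
    }
  }
  minus <- tss$strand == "-"
  if (any(minus)) out[minus, ] <- out[minus, nb:1, drop = FALSE]
  out
}
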
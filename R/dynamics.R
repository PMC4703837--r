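#' Bin a chromatin-state segmentation
#'
#' Assigns each fixed-width bin the state covering the majority of its
#' bases; ties break to the state listed earlier in `states`. Bases not
#' covered by any segment count toward `unmodified`. Terminal scaffold
#' bins may be shorter than `bin`.
#'
#' @param segmentation data.frame (scaffold, start, end, state),
#'   non-overlapping within a stage.
#' @param scaffold_lengths Named vector of scaffold lengths.
#' @param bin Bin width in bp (default 200).
#' @param states State labels in priority order for tie-breaking;
#'   defaults to order of first appearance with `unmodified` last.
#' @param unmodified Label for unannotated bases.
#' @return data.frame (scaffold, start, end, state), one row per bin.
#' @export
bin_segmentation <- function(segmentation, scaffold_lengths, bin = 200L,
                             states = NULL, unmodified = "Unmodified") {
  seg <- segmentation[order(segmentation$scaffold, segmentation$start), ,
                      drop = FALSE]
  ov <- which(seg$scaffold[-1] == seg$scaffold[-nrow(seg)] &
                seg$start[-1] < seg$end[-nrow(seg)])
  if (length(ov)) {
    stop("overlapping segmentation intervals on ", seg$scaffold[ov[1] + 1],
         " at ", seg$start[ov[1] + 1])
  }
  if (is.null(states)) states <- c(setdiff(unique(seg$state), unmodified),
                                   unmodified)
  bins <- do.call(rbind, lapply(names(scaffold_lengths), function(sc) {
    L <- scaffold_lengths[[sc]]
    st <- seq(0L, L - 1L, by = bin)
    data.frame(scaffold = sc, start = st, end = pmin(st + bin, L),
               stringsAsFactors = FALSE)
  }))
  lab <- rep(unmodified, nrow(bins))
  # accumulate covered bp per (bin, state); majority wins, priority breaks ties
  cov <- matrix(0, nrow(bins), length(states), dimnames = list(NULL, states))
  # bins are laid out scaffold-blockwise in order of scaffold_lengths
  offs <- cumsum(c(0, ceiling(unlist(scaffold_lengths) / bin)))
  names(offs) <- c(names(scaffold_lengths), "_end")
  bin_index <- function(sc, pos) offs[[sc]] + pos %/% bin + 1L
  for (i in seq_len(nrow(seg))) {
    sc <- seg$scaffold[i]
    if (!sc %in% names(scaffold_lengths)) next
    s <- seg$start[i]; e <- min(seg$end[i], scaffold_lengths[[sc]])
    if (e <= s) next
    b0 <- s %/% bin; b1 <- (e - 1L) %/% bin
    idx <- bin_index(sc, (b0:b1) * bin)
    bs <- (b0:b1) * bin
    w <- pmin(e, bs + bin) - pmax(s, bs)
    cov[cbind(idx, match(seg$state[i], states))] <-
      cov[cbind(idx, match(seg$state[i], states))] + w
  }
  covered <- rowSums(cov)
  width <- bins$end - bins$start
  cov[, unmodified] <- cov[, unmodified] + (width - covered)
  lab <- states[max.col(cov, ties.method = "first")]
  bins$state <- lab
  bins
}

#' Chromatin-state matrix across stages
#'
#' Bins every stage's segmentation onto one shared 200-bp grid,
#' producing the bins x stages label matrix `a(i, j)`.
#'
#' @param segmentations Named list (stage -> segmentation data.frame).
#' @param scaffold_lengths Named vector of scaffold lengths.
#' @param bin Bin width (default 200).
#' @param states Optional state priority order (see
#'   [bin_segmentation()]).
#' @param unmodified Label for unannotated bases.
#' @return List with `bins` (coordinates) and `labels` (character
#'   matrix, one column per stage).
#' @export
state_matrix <- function(segmentations, scaffold_lengths, bin = 200L,
                         states = NULL, unmodified = "Unmodified") {
  cols <- lapply(segmentations, bin_segmentation,
                 scaffold_lengths = scaffold_lengths, bin = bin,
                 states = states, unmodified = unmodified)
  labels <- do.call(cbind, lapply(cols, `[[`, "state"))
  colnames(labels) <- names(segmentations)
  list(bins = cols[[1]][c("scaffold", "start", "end")], labels = labels)
}

#' Modified-genome mask
#'
#' Bins whose chromatin state is other than unmodified in any stage —
#' the denominator of all coverage and flow percentages.
#'
#' @param labels bins x stages label matrix.
#' @param unmodified Unmodified label.
#' @return Logical vector over bins.
#' @export
modified_genome_mask <- function(labels, unmodified = "Unmodified") {
  rowSums(labels != unmodified) > 0
}

#' State coverage per stage within the modified genome
#'
#' Base-pair fraction of the masked genome occupied by each state at
#' each stage; columns sum to 1.
#'
#' @param labels bins x stages label matrix.
#' @param mask Logical bin mask (see [modified_genome_mask()]).
#' @param widths Bin widths in bp (recycled; default 200).
#' @return states x stages numeric matrix of fractions.
#' @export
coverage_per_stage <- function(labels, mask, widths = 200L) {
  if (!any(mask)) stop("empty modified-genome mask")
  widths <- rep(widths, length.out = nrow(labels))
  lw <- widths[mask]
  lm <- labels[mask, , drop = FALSE]
  states <- sort(unique(as.vector(labels)))
  out <- sapply(seq_len(ncol(lm)), function(j) {
    bp <- tapply(lw, factor(lm[, j], levels = states), sum, default = 0)
    bp / sum(lw)
  })
  rownames(out) <- states
  colnames(out) <- colnames(labels)
  out
}

#' Base-pair transition flows between consecutive stages
#'
#' For each consecutive stage pair, the bp moving from every state to
#' every state within the modified genome, suitable for Sankey/alluvial
#' rendering. Outflows of a state reconcile exactly with its coverage
#' at the earlier stage, and total flow equals the modified-genome
#' size.
#'
#' @param labels bins x stages label matrix (>= 2 stages).
#' @param mask Logical bin mask.
#' @param widths Bin widths in bp (recycled; default 200).
#' @param focus Optional state set: keep only flows touching it.
#' @return List with `flows` (data.frame: from_stage, to_stage, from,
#'   to, bp) and `sankey` (nodes/links lists, node ids `state@stage`).
#' @export
transition_flows <- function(labels, mask, widths = 200L, focus = NULL) {
  if (ncol(labels) < 2) stop("need at least two stages")
  widths <- rep(widths, length.out = nrow(labels))
  lm <- labels[mask, , drop = FALSE]
  lw <- widths[mask]
  stages <- colnames(labels)
  rows <- list()
  for (j in seq_len(ncol(lm) - 1)) {
    bp <- tapply(lw, list(from = lm[, j], to = lm[, j + 1]), sum)
    df <- as.data.frame(as.table(bp), stringsAsFactors = FALSE)
    names(df) <- c("from", "to", "bp")
    df <- df[!is.na(df$bp) & df$bp > 0, , drop = FALSE]
    df$from_stage <- stages[j]
    df$to_stage <- stages[j + 1]
    rows[[j]] <- df[c("from_stage", "to_stage", "from", "to", "bp")]
  }
  flows <- do.call(rbind, rows)
  if (!is.null(focus)) {
    flows <- flows[flows$from %in% focus | flows$to %in% focus, , drop = FALSE]
  }
  nodes <- unique(c(paste0(flows$from, "@", flows$from_stage),
                    paste0(flows$to, "@", flows$to_stage)))
  links <- data.frame(
    source = paste0(flows$from, "@", flows$from_stage),
    target = paste0(flows$to, "@", flows$to_stage),
    value = flows$bp, stringsAsFactors = FALSE
  )
  rownames(flows) <- NULL
  list(flows = flows, sankey = list(nodes = nodes, links = links))
}
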
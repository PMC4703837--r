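#' Coverage-weighted methylation level
#'
#' `sum(methylated) / sum(total)` over covered CpGs — each read, not
#' each CpG, carries equal weight, which is robust at low coverage.
#' Zero-coverage CpGs drop out of both sums.
#'
#' @param meth Methylated read counts per CpG.
#' @param total Total read counts per CpG.
#' @return Weighted level in [0, 1], or `NA` when nothing is covered.
#' @export
weighted_methylation <- function(meth, total) {
  if (any(meth > total, na.rm = TRUE) || any(meth < 0, na.rm = TRUE)) {
    stop("need 0 <= methylated <= total")
  }
  covered <- !is.na(total) & total > 0
  if (!any(covered)) return(NA_real_)
  sum(meth[covered]) / sum(total[covered])
}

#' Promoter methylation from a CpG call table
#'
#' Applies [weighted_methylation()] to the CpGs falling in each
#' promoter window and reports the number of covered CpGs.
#'
#' @param cpg data.frame (scaffold, pos, meth, total).
#' @param promoters data.frame (gene_id, scaffold, start, end).
#' @return data.frame (gene_id, weighted_methylation, n_cpgs).
#' @export
promoter_methylation <- function(cpg, promoters) {
  out <- data.frame(gene_id = promoters$gene_id,
                    weighted_methylation = NA_real_, n_cpgs = 0L,
                    stringsAsFactors = FALSE)
  if (!nrow(cpg)) return(out)
  cg <- GenomicRanges::GRanges(cpg$scaffold,
                               IRanges::IRanges(cpg$pos + 1L, cpg$pos + 1L))
  hits <- GenomicRanges::findOverlaps(peaks_to_granges(promoters), cg)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  for (i in unique(q)) {
    rows <- s[q == i]
    out$weighted_methylation[i] <- weighted_methylation(cpg$meth[rows],
                                                        cpg$total[rows])
    out$n_cpgs[i] <- sum(cpg$total[rows] > 0)
  }
  out
}

#' CpG dinucleotide density of a sequence window
#'
#' Observed CG dinucleotides per bp by default, or the
#' observed/expected ratio `CG * L / (C * G)`.
#'
#' @param sequence Nucleotide string (A/C/G/T, case-insensitive; N
#'   allowed unless `strict`).
#' @param method `"per_bp"` or `"obs_exp"`.
#' @param strict Error on non-ACGTN characters (default TRUE).
#' @return Density value.
#' @export
cpg_density <- function(sequence, method = c("per_bp", "obs_exp"),
                        strict = TRUE) {
  method <- match.arg(method)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L == 0) stop("window length must be positive")
  if (strict && grepl("[^ACGTN]", sequence)) {
    stop("non-nucleotide characters in sequence")
  }
  cg <- lengths(gregexpr("CG", sequence, fixed = TRUE))
  cg[vapply(gregexpr("CG", sequence, fixed = TRUE),
            function(g) g[1] == -1, logical(1))] <- 0L
  if (method == "per_bp") return(cg / L)
  nc <- lengths(gregexpr("C", sequence, fixed = TRUE))
  ng <- lengths(gregexpr("G", sequence, fixed = TRUE))
  if (nc == 0 || ng == 0) return(0)
  cg * L / (nc * ng)
}

#' Bio-CAP hypomethylation call
#'
#' A promoter is hypomethylated when the Bio-CAP / input RPKM ratio on
#' the +/-1-kb promoter window exceeds 1 (Bio-CAP captures
#' non-methylated CpGs, so enrichment over input indicates a
#' hypomethylated island).
#'
#' @param biocap_rpkm Bio-CAP RPKM on the promoter window.
#' @param input_rpkm Input RPKM on the same window (> 0).
#' @return Logical flag(s).
#' @export
biocap_hypomethylation_call <- function(biocap_rpkm, input_rpkm) {
  if (any(input_rpkm <= 0)) stop("input RPKM must be positive")
  (biocap_rpkm / input_rpkm) > 1
}

#' Joint MaD/ZyD x methylation table
#'
#' Cross-tabulates gene-level consensus labels against promoter
#' methylation class (hypomethylated when the weighted level is below
#' `hypo_cutoff`, or using a supplied logical call), with per-cell
#' median methylation.
#'
#' @param gene_labels data.frame (gene_id, label).
#' @param methylation data.frame (gene_id, weighted_methylation) or
#'   with a logical `hypomethylated` column.
#' @param hypo_cutoff Weighted-level cutoff for the bisulfite-based
#'   rule (default 0.2), ignored when `hypomethylated` is present.
#' @return List with `counts` (label x class table) and `cells`
#'   (per-cell n and median level).
#' @export
joint_table <- function(gene_labels, methylation, hypo_cutoff = 0.2) {
  m <- merge(gene_labels, methylation, by = "gene_id")
  if (is.null(m$hypomethylated)) {
    m$hypomethylated <- m$weighted_methylation < hypo_cutoff
  }
  m <- m[!is.na(m$hypomethylated), , drop = FALSE]
  m$meth_class <- ifelse(m$hypomethylated, "hypo", "hyper")
  labels <- c("MaD", "ZyD", "ND", "unmarked")
  counts <- table(factor(m$label, levels = labels),
                  factor(m$meth_class, levels = c("hypo", "hyper")))
  cells <- do.call(rbind, lapply(labels, function(lb) {
    do.call(rbind, lapply(c("hypo", "hyper"), function(mc) {
      sub <- m[m$label == lb & m$meth_class == mc, , drop = FALSE]
      data.frame(label = lb, meth_class = mc, n = nrow(sub),
                 median_methylation = if (nrow(sub) &&
                                          !is.null(sub$weighted_methylation))
                   stats::median(sub$weighted_methylation) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  list(counts = counts, cells = cells)
}
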
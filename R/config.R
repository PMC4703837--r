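#' Developmental stage labels, in temporal order
#'
#' The ordered stage tokens used throughout the pipeline. Stage 11 is the
#' alpha-amanitin comparison stage: treated embryos are collected when their
#' sibling controls reach mid-gastrulation.
#'
#' @return Character vector of stage labels in developmental order.
#' @export
stage_levels <- function() {
  c("8", "9", "10.5", "11", "12", "12.5", "16", "30")
}

#' Position of a stage label in developmental order
#'
#' @param stage Character vector of stage labels.
#' @return Integer index into [stage_levels()].
#' @export
stage_index <- function(stage) {
  idx <- match(as.character(stage), stage_levels())
  if (anyNA(idx)) {
    stop("unknown stage label(s): ",
         paste(unique(stage[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Pipeline configuration
#'
#' Collects every numeric threshold of the analysis with defaults equal to
#' the published values: M-value cutoff 1, -log10(P) cutoffs 5 (H3K27me3)
#' and 1.3 (H3K4me3, p300), relative-RPKM floor 1, reference stages 10.5
#' (H3K4me3, p300) and 12 (H3K27me3), input-exclusion rule (>= 75% overlap
#' with 1-kb bins holding > 65 input reads), 12.5-kb enhancer stitching,
#' z > 13 motif selection, promoter windows (+/-250 bp gene-level H3K4me3,
#' +/-2.5 kb H3K27me3, +/-100 bp methylation x H3K4me3, +/-1 kb Bio-CAP),
#' and GREAT basal-plus-extension defaults (5 kb up, 1 kb down, 1 Mb cap).
#'
#' @param ... Named overrides of any default listed above.
#' @return A `madzyd_config` list.
#' @examples
#' cfg <- pipeline_config(seed = 7)
#' cfg$m_cutoff
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    scaffold_whitelist  = paste0("scaffold_", 1:10),
    # signal normalization
    input_bin_size          = 1000L,
    input_overlap_fraction  = 0.75,
    input_count_threshold   = 65,
    background_n_regions    = 10000L,
    background_percentile   = 0.95,
    literal_background_filter = FALSE,
    library_size_scope      = "all_aligned",  # or "whitelisted"
    # MA-based differential model
    pseudocount         = 0.5,
    manorm_on_raw       = TRUE,
    # classifier thresholds
    m_cutoff            = 1.0,
    neg_log10_p_cutoff  = c(H3K4me3 = 1.3, H3K27me3 = 5, p300 = 1.3),
    rel_rpkm_min        = 1.0,
    reference_stage     = c(H3K4me3 = "10.5", H3K27me3 = "12", p300 = "10.5"),
    amanitin_stage      = "11",
    control_cutoff_waiver = list(H3K27me3 = "rep1"),
    # gene-level windows (bp, from TSS)
    promoter_h3k4me3    = 250L,
    promoter_h3k27me3   = 2500L,
    methylation_window_h3k4me3  = 100L,
    methylation_window_h3k27me3 = 2500L,
    biocap_window       = 1000L,
    # GREAT regulatory domains
    great_basal_up      = 5000L,
    great_basal_down    = 1000L,
    great_max_extension = 1000000L,
    # enhancer clusters
    stitch_distance     = 12500L,
    # motif activity
    z_threshold         = 13,
    ridge_lambda        = NA_real_,   # NA = choose by cross-validation
    log_signal          = TRUE,
    # methylation
    hypomethylation_level_cutoff = 0.2,
    cpg_density_method  = "per_bp",   # or "obs_exp"
    # chromatin dynamics
    state_bin_size      = 200L,
    # misc
    seed                = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == "")) {
      stop("unknown or unnamed configuration field(s): ",
           paste(bad, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  class(cfg) <- "madzyd_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg A `madzyd_config` object.
#' @return `cfg`, invisibly, if valid; otherwise an error.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "madzyd_config"))
  num_pos <- c("input_bin_size", "input_count_threshold", "pseudocount",
               "m_cutoff", "rel_rpkm_min", "promoter_h3k4me3",
               "promoter_h3k27me3", "biocap_window", "great_basal_up",
               "great_basal_down", "great_max_extension", "stitch_distance",
               "z_threshold", "state_bin_size")
  for (f in num_pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0) {
      stop("configuration field '", f, "' must be a positive scalar")
    }
  }
  if (cfg$input_overlap_fraction <= 0 || cfg$input_overlap_fraction > 1) {
    stop("input_overlap_fraction must be in (0, 1]")
  }
  if (cfg$background_percentile <= 0 || cfg$background_percentile > 1) {
    stop("background_percentile must be in (0, 1]")
  }
  if (any(cfg$neg_log10_p_cutoff <= 0)) {
    stop("neg_log10_p_cutoff values must be positive")
  }
  if (!all(cfg$reference_stage %in% stage_levels())) {
    stop("reference_stage values must be known stage labels")
  }
  if (!length(cfg$scaffold_whitelist)) stop("scaffold_whitelist is empty")
  invisible(cfg)
}

#' Write a configuration to JSON
#'
#' @param cfg A `madzyd_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  validate_config(cfg)
  out <- lapply(unclass(cfg), function(v) {
    # named vectors must become JSON objects, not bare arrays
    if (is.atomic(v) && !is.null(names(v))) as.list(v) else v
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read a configuration from JSON
#'
#' Round-trips losslessly with [write_config()].
#'
#' @param path JSON file written by [write_config()].
#' @return A `madzyd_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- pipeline_config()
  for (nm in names(raw)) {
    val <- raw[[nm]]
    tmpl <- cfg[[nm]]
    if (is.null(val)) val <- tmpl[NA][1]       # JSON null -> typed NA
    if (is.atomic(tmpl) && is.list(val)) val <- unlist(val)
    if (is.integer(tmpl)) {
      val <- stats::setNames(as.integer(val), names(val))
    } else if (is.double(tmpl)) {
      val <- stats::setNames(as.double(val), names(val))
    } else if (is.character(tmpl)) {
      val <- stats::setNames(as.character(val), names(val))
    }
    if (is.list(tmpl) && !is.list(val)) val <- as.list(val)
    cfg[[nm]] <- val
  }
  validate_config(cfg)
  cfg
}
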
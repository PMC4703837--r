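#' Simulation configuration
#'
#' Parameters of the synthetic-data generators. Defaults describe the
#' benchmark condition used throughout the package: 2,000 peaks of which
#' 60% are maternally defined (MaD), 25% zygotically defined (ZyD, 8-fold
#' depleted upon transcription blockade) and 15% ambiguous (depleted in
#' exactly one replicate), negative-binomial counts with mean 30 and
#' dispersion 0.1, two replicates.
#'
#' @param ... Named overrides of any default.
#' @return A `madzyd_simconfig` list.
#' @export
simulation_config <- function(...) {
  sc <- list(
    # genome
    n_scaffolds       = 4L,
    scaffold_length   = 10000000L,
    n_genes           = 200L,
    min_gene_spacing  = 20000L,
    # amanitin experiment
    n_peaks             = 2000L,
    peak_width          = 500L,
    fraction_mad        = 0.60,
    fraction_zyd        = 0.25,
    fraction_ambiguous  = 0.15,
    fraction_zyd_late   = 0,     # share of ZyD peaks that first appear after stage 11
    mean_reads_per_peak = 30,
    dispersion          = 0.1,
    depletion_factor    = 8,
    n_replicates        = 2L,
    background_mean     = 2,
    n_background        = 1000L,
    library_size        = 1000000,
    # p300 enhancer-cluster landscape
    ec_stages            = c("9", "10.5", "12.5", "16", "30"),
    n_clusters           = 20L,
    peaks_per_cluster    = 5L,
    intra_cluster_spacing = 5000L,
    n_singletons         = 200L,
    singleton_min_gap    = 25000L,
    cluster_signal_shift = 20,
    # methylome
    hypo_beta     = c(1, 19),
    hyper_beta    = c(8, 2),
    cpgs_hypo     = 20,
    cpgs_hyper    = 5,
    coverage_mean = 10,
    # motif activity
    n_motif_peaks      = 500L,
    n_motifs           = 20L,
    n_active_motifs    = 3L,
    motif_count_mean   = 2,
    activity_amplitude = 0.5,
    motif_noise_sd     = 0.1,
    n_motif_stages     = 5L,
    # chromatin states
    state_stages     = c("9", "10.5", "12.5", "16", "30"),
    n_state_bins     = 20000L,
    state_names      = c("Polycomb", "Poised", "Enhancer", "Transcribed",
                         "Promoter", "Heterochromatin", "Unmodified"),
    state_stay_prob  = 0.88,
    initial_unmodified = 0.5,
    seed             = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(sc))
    if (length(bad)) stop("unknown simulation field(s): ", paste(bad, collapse = ", "))
    sc[names(dots)] <- dots
  }
  fr <- sc$fraction_mad + sc$fraction_zyd + sc$fraction_ambiguous
  if (any(c(sc$fraction_mad, sc$fraction_zyd, sc$fraction_ambiguous) < 0) || fr > 1 + 1e-9) {
    stop("class fractions must be non-negative and sum to at most 1")
  }
  if (sc$depletion_factor <= 1) stop("depletion_factor must exceed 1")
  class(sc) <- "madzyd_simconfig"
  sc
}

# NB counts; dispersion is the quadratic overdispersion coefficient
# (var = mu + dispersion * mu^2); dispersion 0 collapses to Poisson.
rcounts <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed %% .Machine$integer.max)
  force(code)
}

#' Simulate scaffolds, genes and promoter windows
#'
#' Places `n_genes` TSSs uniformly over the scaffolds with a minimum
#' inter-gene spacing; strands alternate deterministically.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed; the generator is a pure function of
#'   (config, seed).
#' @return List with `scaffolds` (name/length data.frame) and `tss`
#'   (gene_id, scaffold, tss, strand).
#' @export
simulate_genome_annotation <- function(config = simulation_config(),
                                       seed = config$seed) {
  n_per <- ceiling(config$n_genes / config$n_scaffolds)
  if (n_per * config$min_gene_spacing > config$scaffold_length) {
    stop("cannot place ", config$n_genes, " genes at spacing ",
         config$min_gene_spacing, " on scaffolds of length ",
         config$scaffold_length)
  }
  scaffolds <- data.frame(
    scaffold = paste0("scaffold_", seq_len(config$n_scaffolds)),
    length = config$scaffold_length,
    stringsAsFactors = FALSE
  )
  tss <- with_seed(seed + 101L, {
    rows <- lapply(seq_len(config$n_scaffolds), function(i) {
      n_here <- length(seq(i, config$n_genes, by = config$n_scaffolds))
      if (!n_here) return(NULL)
      # draw spacings >= min_gene_spacing, rescale leftovers uniformly
      slack <- config$scaffold_length - n_here * config$min_gene_spacing
      gaps <- stats::runif(n_here)
      gaps <- gaps / sum(gaps) * slack * 0.9
      pos <- cumsum(config$min_gene_spacing + gaps)
      data.frame(
        gene_id = sprintf("gene_%04d", seq(i, config$n_genes, by = config$n_scaffolds)),
        scaffold = scaffolds$scaffold[i],
        tss = as.integer(round(pos)),
        strand = rep(c("+", "-"), length.out = n_here),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
  tss <- tss[order(tss$gene_id), , drop = FALSE]
  rownames(tss) <- NULL
  list(scaffolds = scaffolds, tss = tss)
}

#' Simulate the transcription-blockade ChIP experiment
#'
#' Generates replicate read counts at peaks for control and
#' alpha-amanitin-injected samples at stage 11, plus a single
#' reference-stage sample, under a negative-binomial model. True-ZyD
#' peaks have their treated mean divided by `depletion_factor` in both
#' replicates; ambiguous peaks are depleted in exactly one replicate;
#' late-emerging ZyD peaks (fraction `fraction_zyd_late` of the ZyD
#' class) carry background-level counts in all stage-11 and reference
#' samples and a first-appearance stage after 11. Background regions
#' receive low counts and supply the background model.
#'
#' Counts follow a hierarchical negative-binomial model: each region
#' carries a latent enrichment propensity `u ~ Gamma(1/dispersion,
#' 1/dispersion)` (unit mean, variance = dispersion) shared across all
#' samples and replicates, and counts are Poisson with mean
#' `u x sample mean`. Marginally every count is negative binomial with
#' the stated mean and dispersion (Poisson when dispersion = 0), while
#' within-region count ratios between samples carry only Poisson noise
#' — reflecting that ChIP overdispersion is dominated by stable
#' region-to-region enrichment differences rather than independent
#' per-sample fluctuations.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return List with `peaks` (counts + first_stage per peak),
#'   `background` (background-region counts), `truth` (peak_id, label),
#'   `samples` (sample names), `library_size`.
#' @export
simulate_amanitin_experiment <- function(config = simulation_config(),
                                         seed = config$seed) {
  n <- config$n_peaks
  n_mad <- round(n * config$fraction_mad)
  n_zyd <- round(n * config$fraction_zyd)
  n_amb <- round(n * config$fraction_ambiguous)
  n_bg_peaks <- n - n_mad - n_zyd - n_amb   # residual: pure-background "peaks"
  labels <- rep(c("MaD", "ZyD", "ambiguous", "background"),
                times = c(n_mad, n_zyd, n_amb, n_bg_peaks))

  with_seed(seed + 202L, {
    labels <- sample(labels)
    n_zyd_late <- round(sum(labels == "ZyD") * config$fraction_zyd_late)
    zyd_idx <- which(labels == "ZyD")
    late <- rep(FALSE, n)
    if (n_zyd_late > 0) late[sample(zyd_idx, n_zyd_late)] <- TRUE

    # evenly strided non-overlapping placement across scaffolds
    per_scaf <- ceiling(n / config$n_scaffolds)
    stride <- floor(config$scaffold_length / (per_scaf + 1))
    if (stride <= config$peak_width) stop("peaks do not fit on scaffolds")
    scaf <- paste0("scaffold_", ((seq_len(n) - 1L) %% config$n_scaffolds) + 1L)
    slot <- ((seq_len(n) - 1L) %/% config$n_scaffolds) + 1L
    start <- as.integer(slot * stride)
    peaks <- data.frame(
      peak_id = sprintf("peak_%05d", seq_len(n)),
      scaffold = scaf, start = start, end = start + config$peak_width,
      stringsAsFactors = FALSE
    )

    mu <- config$mean_reads_per_peak
    bg <- config$background_mean
    dep <- config$depletion_factor
    disp <- config$dispersion
    present <- labels %in% c("MaD", "ZyD", "ambiguous") & !late
    # which replicate carries the depletion for ambiguous peaks
    amb_rep <- ifelse(stats::runif(n) < 0.5, 1L, 2L)
    # latent per-peak enrichment propensity, shared across samples
    u <- if (disp > 0) stats::rgamma(n, shape = 1 / disp, rate = 1 / disp)
         else rep(1, n)

    mean_for <- function(sample, rep) {
      m <- rep(bg, n)
      m[present] <- mu
      if (sample == "aman") {
        dep_full <- labels == "ZyD" & !late
        m[dep_full] <- mu / dep
        dep_amb <- labels == "ambiguous" & amb_rep == rep
        m[dep_amb] <- mu / dep
      }
      m * u
    }
    peaks$ctrl_rep1 <- stats::rpois(n, mean_for("ctrl", 1L))
    peaks$ctrl_rep2 <- stats::rpois(n, mean_for("ctrl", 2L))
    peaks$aman_rep1 <- stats::rpois(n, mean_for("aman", 1L))
    peaks$aman_rep2 <- stats::rpois(n, mean_for("aman", 2L))
    peaks$ref <- stats::rpois(n, mean_for("ctrl", 1L))
    peaks$first_stage <- ifelse(late, "12.5",
                                ifelse(present, sample(c("9", "10.5"), n, replace = TRUE), NA))
    peaks$first_stage[labels == "background"] <- NA

    n_bg <- config$n_background
    bg_start <- as.integer(seq(floor(stride / 2), by = stride,
                               length.out = ceiling(n_bg / config$n_scaffolds)))
    bgdf <- data.frame(
      region_id = sprintf("bg_%05d", seq_len(n_bg)),
      scaffold = paste0("scaffold_", ((seq_len(n_bg) - 1L) %% config$n_scaffolds) + 1L),
      start = bg_start[((seq_len(n_bg) - 1L) %/% config$n_scaffolds) + 1L],
      stringsAsFactors = FALSE
    )
    bgdf$end <- bgdf$start + config$peak_width
    u_bg <- if (disp > 0) stats::rgamma(n_bg, shape = 1 / disp, rate = 1 / disp)
            else rep(1, n_bg)
    for (s in c("ctrl_rep1", "ctrl_rep2", "aman_rep1", "aman_rep2", "ref")) {
      bgdf[[s]] <- stats::rpois(n_bg, bg * u_bg)
    }

    list(
      peaks = peaks,
      background = bgdf,
      truth = data.frame(peak_id = peaks$peak_id, label = labels,
                         late = late, stringsAsFactors = FALSE),
      samples = c("ctrl_rep1", "ctrl_rep2", "aman_rep1", "aman_rep2", "ref"),
      library_size = config$library_size
    )
  })
}

#' Simulate a multi-stage p300 landscape with planted enhancer clusters
#'
#' Clusters are seeded at the earliest stage by a single peak; member
#' peaks (inter-peak gap at most `intra_cluster_spacing`) accrue at later
#' stages, so cluster coverage of the final region grows over
#' development. Isolated singleton peaks are scattered at least
#' `singleton_min_gap` apart. Cluster-member signal is background
#' (Exp(1)) plus `cluster_signal_shift`; singleton signal is background
#' only.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return List with `peaks` (stage, peak_id, coords, signal,
#'   cluster_id NA for singletons, is_seed) and `truth`
#'   (cluster_id, scaffold, start, end, seed_peak_id).
#' @export
simulate_p300_stages <- function(config = simulation_config(),
                                 seed = config$seed) {
  stages <- config$ec_stages
  k <- config$peaks_per_cluster
  w <- config$peak_width
  gap <- config$intra_cluster_spacing
  footprint <- k * w + (k - 1L) * gap
  cluster_stride <- footprint + 4L * config$singleton_min_gap
  per_scaf <- ceiling(config$n_clusters / config$n_scaffolds)
  if (per_scaf * cluster_stride > config$scaffold_length) {
    stop("cluster footprint exceeds scaffold length")
  }
  with_seed(seed + 303L, {
    rows <- list(); truth <- list()
    for (ci in seq_len(config$n_clusters)) {
      scaf <- paste0("scaffold_", ((ci - 1L) %% config$n_scaffolds) + 1L)
      base <- as.integer((((ci - 1L) %/% config$n_scaffolds)) * cluster_stride +
                           config$singleton_min_gap)
      starts <- base + (seq_len(k) - 1L) * (w + gap)
      # member j becomes visible from stage ceil(j * n_stages / k); the
      # seed peak (member 1) is present from the first stage
      appear <- pmax(1L, ceiling(seq_len(k) / k * length(stages)))
      appear[1] <- 1L
      for (si in seq_along(stages)) {
        vis <- which(appear <= si)
        if (!length(vis)) next
        rows[[length(rows) + 1L]] <- data.frame(
          stage = stages[si],
          peak_id = sprintf("p300_c%03d_m%02d_s%s", ci, vis, stages[si]),
          scaffold = scaf, start = starts[vis], end = starts[vis] + w,
          signal = stats::rexp(length(vis), 1) + config$cluster_signal_shift,
          cluster_id = sprintf("cluster_%03d", ci),
          is_seed = vis == 1L,
          stringsAsFactors = FALSE
        )
      }
      truth[[ci]] <- data.frame(
        cluster_id = sprintf("cluster_%03d", ci), scaffold = scaf,
        start = starts[1], end = starts[k] + w,
        seed_peak_id = sprintf("p300_c%03d_m01_s%s", ci, stages[1]),
        stringsAsFactors = FALSE
      )
    }
    # singletons: strided placement in the tail half of each scaffold
    n_s <- config$n_singletons
    s_stride <- config$singleton_min_gap + w
    offset <- as.integer(per_scaf * cluster_stride + config$singleton_min_gap)
    n_fit <- max(0L, floor((config$scaffold_length - offset) / s_stride) - 1L)
    if (ceiling(n_s / config$n_scaffolds) > n_fit) {
      stop("singletons do not fit outside the cluster territory")
    }
    s_scaf <- paste0("scaffold_", ((seq_len(n_s) - 1L) %% config$n_scaffolds) + 1L)
    s_start <- offset + (((seq_len(n_s) - 1L) %/% config$n_scaffolds)) * s_stride
    for (si in seq_along(stages)) {
      rows[[length(rows) + 1L]] <- data.frame(
        stage = stages[si],
        peak_id = sprintf("p300_s%04d_s%s", seq_len(n_s), stages[si]),
        scaffold = s_scaf, start = as.integer(s_start), end = as.integer(s_start + w),
        signal = stats::rexp(n_s, 1),
        cluster_id = NA_character_, is_seed = FALSE,
        stringsAsFactors = FALSE
      )
    }
    peaks <- do.call(rbind, rows)
    peaks <- peaks[order(peaks$stage, peaks$scaffold, peaks$start), , drop = FALSE]
    rownames(peaks) <- NULL
    list(peaks = peaks, truth = do.call(rbind, truth), stages = stages)
  })
}

#' Simulate a promoter methylome
#'
#' Hypomethylated promoters draw per-CpG methylation from a low-mode
#' Beta, hypermethylated from a high-mode Beta; CpG density is higher in
#' hypomethylated promoters; per-CpG coverage is Poisson. When a truth
#' table from [simulate_amanitin_experiment()] gene labels is supplied,
#' MaD promoters are hypomethylated and ZyD promoters hypermethylated,
#' emulating the coupling between maternal definition and promoter
#' DNA-methylation state.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @param promoters data.frame with gene_id, scaffold, start, end;
#'   defaults to promoters of [simulate_genome_annotation()].
#' @param meth_class Optional character vector ("hypo"/"hyper") per
#'   promoter; defaults to a random half/half split.
#' @return List with `cpg` (scaffold, pos, meth, total) and `truth`
#'   (gene_id, meth_class, true_level).
#' @export
simulate_methylome <- function(config = simulation_config(),
                               seed = config$seed,
                               promoters = NULL, meth_class = NULL) {
  if (is.null(promoters)) {
    ann <- simulate_genome_annotation(config, seed)
    promoters <- promoter_windows(ann$tss, 500L)
  }
  n <- nrow(promoters)
  with_seed(seed + 404L, {
    if (is.null(meth_class)) {
      meth_class <- sample(rep(c("hypo", "hyper"), length.out = n))
    }
    stopifnot(length(meth_class) == n, all(meth_class %in% c("hypo", "hyper")))
    rows <- vector("list", n)
    lev <- numeric(n)
    for (i in seq_len(n)) {
      hypo <- meth_class[i] == "hypo"
      n_cpg <- stats::rpois(1, if (hypo) config$cpgs_hypo else config$cpgs_hyper)
      if (n_cpg == 0) { lev[i] <- NA; next }
      ab <- if (hypo) config$hypo_beta else config$hyper_beta
      frac <- stats::rbeta(n_cpg, ab[1], ab[2])
      total <- stats::rpois(n_cpg, config$coverage_mean)
      meth <- stats::rbinom(n_cpg, total, frac)
      pos <- sort(sample(seq(promoters$start[i], promoters$end[i] - 1L), n_cpg))
      rows[[i]] <- data.frame(
        scaffold = promoters$scaffold[i], pos = pos,
        meth = meth, total = total, gene_id = promoters$gene_id[i],
        stringsAsFactors = FALSE
      )
      lev[i] <- if (sum(total) > 0) sum(meth) / sum(total) else NA
    }
    list(
      cpg = do.call(rbind, rows),
      truth = data.frame(gene_id = promoters$gene_id,
                         meth_class = meth_class, true_level = lev,
                         stringsAsFactors = FALSE)
    )
  })
}

#' Simulate a motif-count/signal dataset with planted activities
#'
#' Site counts N (peaks x motifs) are Poisson; the signal matrix is
#' E = peak offset + stage offset + N A + Gaussian noise. Exactly
#' `n_active_motifs` motifs carry nonzero activity; active rows are
#' centered across stages (the model identifies activities only up to a
#' per-motif constant).
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @return List with `N` (counts), `E` (signal), `A_true`
#'   (motifs x stages), `active` (motif ids with planted activity).
#' @export
simulate_motif_dataset <- function(config = simulation_config(),
                                   seed = config$seed) {
  p <- config$n_motif_peaks; m <- config$n_motifs; s <- config$n_motif_stages
  with_seed(seed + 505L, {
    N <- matrix(stats::rpois(p * m, config$motif_count_mean), p, m,
                dimnames = list(sprintf("peak_%04d", seq_len(p)),
                                sprintf("motif_%02d", seq_len(m))))
    A <- matrix(0, m, s, dimnames = list(colnames(N), paste0("stage_", seq_len(s))))
    active <- sort(sample(m, config$n_active_motifs))
    for (j in active) {
      row <- stats::rnorm(s, 0, config$activity_amplitude)
      A[j, ] <- row - mean(row)
    }
    peak_off <- stats::rnorm(p, 5, 1)
    stage_off <- stats::rnorm(s, 0, 1)
    E <- outer(peak_off, rep(1, s)) + outer(rep(1, p), stage_off) + N %*% A +
      matrix(stats::rnorm(p * s, 0, config$motif_noise_sd), p, s)
    dimnames(E) <- list(rownames(N), colnames(A))
    list(N = N, E = E, A_true = A, active = colnames(N)[active])
  })
}

#' Simulate per-stage chromatin-state segmentations
#'
#' Each 200-bp bin evolves across stages as a Markov chain over the
#' chromatin-state groups (Polycomb, poised, p300 enhancer, transcribed,
#' promoter, heterochromatin, unmodified) with the configured
#' stage-pair transition matrix, and is emitted as merged same-state
#' intervals per stage.
#'
#' @param config A [simulation_config()].
#' @param seed Integer seed.
#' @param transition Optional states x states transition matrix (rows sum
#'   to 1), used for every consecutive stage pair; default sticky matrix
#'   with stay probability `state_stay_prob`.
#' @return List with `segmentations` (named list of per-stage
#'   scaffold/start/end/state data.frames), `labels` (bins x stages true
#'   label matrix), `bins` (bin coordinates), `transition`.
#' @export
simulate_state_segmentations <- function(config = simulation_config(),
                                         seed = config$seed,
                                         transition = NULL) {
  states <- config$state_names
  ns <- length(states)
  if (is.null(transition)) {
    stay <- config$state_stay_prob
    transition <- matrix((1 - stay) / (ns - 1), ns, ns,
                         dimnames = list(states, states))
    diag(transition) <- stay
  }
  if (any(abs(rowSums(transition) - 1) > 1e-9)) {
    stop("transition matrix rows must sum to 1")
  }
  n_bins <- config$n_state_bins
  bw <- 200L
  per_scaf <- ceiling(n_bins / config$n_scaffolds)
  bins <- data.frame(
    scaffold = paste0("scaffold_", rep(seq_len(config$n_scaffolds),
                                       each = per_scaf))[seq_len(n_bins)],
    start = as.integer((rep(seq_len(per_scaf), config$n_scaffolds)[seq_len(n_bins)] - 1L) * bw),
    stringsAsFactors = FALSE
  )
  bins$end <- bins$start + bw
  stages <- config$state_stages
  with_seed(seed + 606L, {
    p0 <- rep((1 - config$initial_unmodified) / (ns - 1), ns)
    names(p0) <- states
    p0["Unmodified"] <- config$initial_unmodified
    labels <- matrix(NA_character_, n_bins, length(stages),
                     dimnames = list(NULL, stages))
    labels[, 1] <- sample(states, n_bins, replace = TRUE, prob = p0)
    for (j in seq_along(stages)[-1]) {
      prev <- labels[, j - 1]
      nxt <- character(n_bins)
      for (s in states) {
        idx <- which(prev == s)
        if (length(idx)) {
          nxt[idx] <- sample(states, length(idx), replace = TRUE,
                             prob = transition[s, ])
        }
      }
      labels[, j] <- nxt
    }
    segs <- lapply(seq_along(stages), function(j) {
      lab <- labels[, j]
      brk <- c(TRUE, lab[-1] != lab[-n_bins] |
                 bins$scaffold[-1] != bins$scaffold[-n_bins])
      run <- cumsum(brk)
      first <- !duplicated(run)
      last <- rev(!duplicated(rev(run)))
      data.frame(
        scaffold = bins$scaffold[first], start = bins$start[first],
        end = bins$end[last], state = lab[first],
        stringsAsFactors = FALSE
      )
    })
    names(segs) <- stages
    list(segmentations = segs, labels = labels, bins = bins,
         transition = transition, stages = stages)
  })
}
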
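test_that("generators are pure functions of (config, seed)", {
  sc <- simulation_config(n_peaks = 200L, n_background = 100L,
                          n_genes = 40L, n_state_bins = 1000L,
                          n_motif_peaks = 50L)
  for (gen in list(simulate_genome_annotation, simulate_amanitin_experiment,
                   simulate_p300_stages, simulate_methylome,
                   simulate_motif_dataset, simulate_state_segmentations)) {
    expect_identical(gen(sc, seed = 7L), gen(sc, seed = 7L))
  }
  a <- simulate_amanitin_experiment(sc, seed = 7L)
  b <- simulate_amanitin_experiment(sc, seed = 8L)
  expect_false(identical(a$peaks$ctrl_rep1, b$peaks$ctrl_rep1))
})

test_that("gene placement respects spacing and fails when impossible", {
  sc <- simulation_config(n_scaffolds = 1L, scaffold_length = 1000000L,
                          n_genes = 10L, min_gene_spacing = 50000L)
  ann <- simulate_genome_annotation(sc, 1L)
  expect_equal(nrow(ann$tss), 10)
  pos <- sort(ann$tss$tss)
  expect_true(all(diff(pos) >= 50000))
  sc_bad <- simulation_config(n_scaffolds = 1L, scaffold_length = 100000L,
                              n_genes = 10L, min_gene_spacing = 50000L)
  expect_error(simulate_genome_annotation(sc_bad, 1L), "cannot place")
})

test_that("blockade counts match the planted depletion structure", {
  sc <- simulation_config()
  sim <- simulate_amanitin_experiment(sc, seed = 3L)
  tr <- sim$truth
  pk <- sim$peaks

  # empirical mean of control counts at present peaks within 3 SE of 30
  present <- tr$label %in% c("MaD", "ZyD", "ambiguous")
  n <- sum(present)
  se <- sqrt((30 + sc$dispersion * 30^2) / n)
  expect_lt(abs(mean(pk$ctrl_rep1[present]) - 30), 3 * se)

  # control/treated mean ratio ~ depletion factor at ZyD, ~1 at MaD
  zyd <- tr$label == "ZyD"
  mad <- tr$label == "MaD"
  expect_lt(abs(mean(pk$ctrl_rep1[zyd]) / mean(pk$aman_rep1[zyd]) - 8), 1)
  expect_lt(abs(mean(pk$ctrl_rep1[mad]) / mean(pk$aman_rep1[mad]) - 1), 0.1)

  # ambiguous peaks are depleted in exactly one replicate
  amb <- tr$label == "ambiguous"
  r1 <- pk$ctrl_rep1[amb] / pmax(pk$aman_rep1[amb], 0.5)
  r2 <- pk$ctrl_rep2[amb] / pmax(pk$aman_rep2[amb], 0.5)
  dep1 <- r1 > 3; dep2 <- r2 > 3
  expect_gt(mean(xor(dep1, dep2)), 0.9)
})

test_that("dispersion 0 with extreme depletion gives the limiting counts", {
  sc <- simulation_config(dispersion = 0, depletion_factor = 1e9,
                          n_peaks = 500L)
  sim <- simulate_amanitin_experiment(sc, 1L)
  zyd <- sim$truth$label == "ZyD"
  expect_true(all(sim$peaks$aman_rep1[zyd] == 0))
  expect_true(all(sim$peaks$aman_rep2[zyd] == 0))
  expect_lt(abs(mean(sim$peaks$ctrl_rep1[zyd]) - 30), 3 * sqrt(30 / sum(zyd)))
})

test_that("p300 clusters stitch into one region and seeds persist", {
  sc <- simulation_config(n_clusters = 4L, peaks_per_cluster = 5L,
                          intra_cluster_spacing = 5000L, n_singletons = 40L)
  sim <- simulate_p300_stages(sc, 2L)
  last <- sim$peaks[sim$peaks$stage == "30", ]
  st <- stitch_peaks(last, 12500L)
  # each planted cluster is one stitched region with all members
  for (i in seq_len(nrow(sim$truth))) {
    hit <- st$scaffold == sim$truth$scaffold[i] &
      st$start <= sim$truth$start[i] & st$end >= sim$truth$end[i]
    expect_equal(sum(hit), 1)
    expect_equal(st$n_members[hit], 5L)
  }
  # singletons (>= 25 kb apart) are never stitched together
  singles <- last[is.na(last$cluster_id), ]
  st_s <- stitch_peaks(singles, 12500L)
  expect_true(all(st_s$n_members == 1L))
  # the seeding peak overlaps the final cluster footprint by construction
  seeds <- sim$peaks[sim$peaks$is_seed & sim$peaks$stage == "9", ]
  expect_true(all(seeds$start >= sim$truth$start[match(seeds$cluster_id,
                                                       sim$truth$cluster_id)]))
})

test_that("methylome modes separate and zero-coverage CpGs drop out", {
  prom <- data.frame(gene_id = sprintf("g%02d", 1:40),
                     scaffold = "scaffold_1",
                     start = seq(0L, by = 10000L, length.out = 40),
                     end = seq(1000L, by = 10000L, length.out = 40))
  cls <- rep(c("hypo", "hyper"), 20)
  sc <- simulation_config(hypo_beta = c(1, 99))
  sim <- simulate_methylome(sc, 5L, promoters = prom, meth_class = cls)
  pm <- promoter_methylation(sim$cpg, prom)
  hypo_levels <- pm$weighted_methylation[cls == "hypo" & pm$n_cpgs >= 5]
  hyper_levels <- pm$weighted_methylation[cls == "hyper" & pm$n_cpgs >= 2]
  expect_true(all(hypo_levels < 0.2))
  expect_gt(stats::median(hyper_levels), 0.5)

  # zero-coverage CpGs do not contribute to the weighted level
  expect_equal(weighted_methylation(c(5, 0), c(10, 0)), 0.5)
})

test_that("state segmentations follow the configured transition matrix", {
  sc <- simulation_config(n_state_bins = 2000L)
  sim <- simulate_state_segmentations(sc, 4L)
  # intervals reproduce the per-bin labels exactly after re-binning
  lens <- tapply(sim$bins$end, sim$bins$scaffold, max)
  sm <- state_matrix(sim$segmentations,
                     stats::setNames(as.numeric(lens), names(lens)),
                     bin = 200L, states = sc$state_names)
  expect_equal(unname(sm$labels), unname(sim$labels))

  # empirical transition frequencies near the configured matrix
  tr <- table(sim$labels[, 1], sim$labels[, 2])
  for (s in rownames(tr)) {
    n <- sum(tr[s, ])
    phat <- tr[s, ] / n
    p <- sim$transition[s, colnames(tr)]
    expect_true(all(abs(phat - p) <= 3 * sqrt(p * (1 - p) / n) + 1e-9))
  }

  # identity transition freezes the chain
  ident <- diag(length(sc$state_names))
  dimnames(ident) <- list(sc$state_names, sc$state_names)
  frozen <- simulate_state_segmentations(sc, 4L, transition = ident)
  expect_true(all(frozen$labels[, 1] == frozen$labels[, 5]))

  bad <- ident; bad[1, 1] <- 0.5
  expect_error(simulate_state_segmentations(sc, 4L, transition = bad),
               "sum to 1")
})

test_that("motif dataset is exact in the noiseless limit", {
  sc <- simulation_config(motif_noise_sd = 0, n_motif_peaks = 60L,
                          n_motifs = 8L)
  sim <- simulate_motif_dataset(sc, 6L)
  # E reconstructs from offsets and N A exactly
  recon <- sim$N %*% sim$A_true
  centered <- sim$E - rowMeans(sim$E) %o% rep(1, ncol(sim$E))
  centered <- sweep(centered, 2, colMeans(centered))
  recon_c <- recon - rowMeans(recon) %o% rep(1, ncol(recon))
  recon_c <- sweep(recon_c, 2, colMeans(recon_c))
  expect_equal(centered, recon_c, tolerance = 1e-10)
  # inactive motifs have exactly zero planted activity
  inactive <- setdiff(rownames(sim$A_true), sim$active)
  expect_true(all(sim$A_true[inactive, ] == 0))
  # zero amplitude removes the motif contribution entirely
  sc0 <- simulation_config(motif_noise_sd = 0, activity_amplitude = 0,
                           n_motif_peaks = 60L, n_motifs = 8L)
  sim0 <- simulate_motif_dataset(sc0, 6L)
  expect_true(all(sim0$A_true == 0))
})
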
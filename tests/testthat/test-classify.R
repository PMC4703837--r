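cfg <- pipeline_config()

test_that("change calls follow the published per-mark thresholds", {
  # H3K4me3: modest p-value clears the 1.3 cutoff -> lost
  c1 <- call_change(1.5, 2.0, rel_control = 2, rel_treated = 2,
                    rel_reference = 2, mark = "H3K4me3", cfg)
  expect_true(c1$is_lost)
  expect_false(c1$is_maintained)

  # same evidence under H3K27me3 (cutoff 5): not lost, maintained
  c2 <- call_change(1.5, 2.0, rel_control = 2, rel_treated = 2,
                    rel_reference = 2, mark = "H3K27me3", cfg)
  expect_false(c2$is_lost)
  expect_true(c2$is_maintained)

  # increased: strong negative M with treated and reference enrichment
  c3 <- call_change(-1.2, 6, rel_control = 0.4, rel_treated = 1.4,
                    rel_reference = 1.2, mark = "H3K27me3", cfg)
  expect_true(c3$is_increased)
  expect_false(c3$is_lost)

  # control-cutoff waiver admits a lost call with weak control signal
  c4 <- call_change(1.5, 6, rel_control = 0.5, rel_treated = 0.2,
                    rel_reference = 2, mark = "H3K27me3", cfg)
  expect_false(c4$is_lost)
  c5 <- call_change(1.5, 6, rel_control = 0.5, rel_treated = 0.2,
                    rel_reference = 2, mark = "H3K27me3", cfg,
                    waive_control = TRUE)
  expect_true(c5$is_lost)

  expect_error(call_change(1, 2, 2, 2, NA, "H3K4me3", cfg), "missing")
  expect_error(call_change(1, 2, 2, 2, 2, "H3K9ac", cfg), "unknown mark")
})

test_that("lost and increased are mutually exclusive; maintained excludes lost", {
  set.seed(5)
  cc <- call_change(rnorm(500, 0, 2), rexp(500, 1 / 3),
                    rel_control = runif(500, 0, 3),
                    rel_treated = runif(500, 0, 3),
                    rel_reference = runif(500, 0, 3),
                    mark = "H3K4me3", cfg)
  expect_false(any(cc$is_lost & cc$is_increased))
  expect_false(any(cc$is_maintained & cc$is_lost))
  expect_true(all(cc$is_unchanged == (!cc$is_lost & !cc$is_increased &
                                        cc$is_maintained)))
})

test_that("raising the M cutoff never converts maintained into lost", {
  set.seed(6)
  m <- rnorm(300, 0.8, 0.8); p <- rexp(300, 1 / 3); r <- runif(300, 0.5, 3)
  strict <- pipeline_config(m_cutoff = 2)
  a <- call_change(m, p, r, r, r, "H3K4me3", cfg)
  b <- call_change(m, p, r, r, r, "H3K4me3", strict)
  expect_false(any(a$is_maintained & b$is_lost))
  expect_true(all(b$is_lost <= a$is_lost))  # stricter cutoff loses fewer
})

test_that("consensus requires both replicates and respects emergence stage", {
  maint <- data.frame(is_lost = FALSE, is_increased = FALSE,
                      is_unchanged = TRUE, is_maintained = TRUE)
  lost <- data.frame(is_lost = TRUE, is_increased = FALSE,
                     is_unchanged = FALSE, is_maintained = FALSE)
  expect_equal(consensus(maint, maint, "9"), "MaD")
  expect_equal(consensus(lost, lost, "10.5"), "ZyD")
  expect_equal(consensus(lost, maint, "9"), "ND")
  # late emergence is ZyD regardless of replicate calls
  expect_equal(consensus(maint, maint, "12.5"), "ZyD")
  expect_equal(consensus(lost, maint, "16"), "ZyD")
  # never detected -> ND
  expect_equal(consensus(maint, maint, NA), "ND")
})

test_that("every peak gets exactly one consensus label", {
  sim <- simulate_amanitin_experiment(simulation_config(n_peaks = 400L), 2L)
  cls <- classify_experiment(sim)
  expect_equal(nrow(cls$table), 400)
  expect_true(all(cls$table$label %in% c("MaD", "ZyD", "ND")))
  expect_equal(sum(table(cls$table$label)), 400)
})

test_that("gene-level H3K4me3 label comes from the promoter window only", {
  tss <- data.frame(gene_id = c("gA", "gB", "gC"), scaffold = "scaffold_1",
                    tss = c(10000L, 50000L, 90000L),
                    strand = c("+", "-", "+"))
  peaks <- data.frame(
    scaffold = "scaffold_1",
    start = c(9900L, 49800L, 49900L, 200000L),
    end = c(10100L, 50100L, 50200L, 200500L),
    label = c("MaD", "MaD", "ZyD", "ZyD"),
    stringsAsFactors = FALSE
  )
  g <- classify_gene_h3k4me3(tss, peaks, flank = 250L)
  expect_equal(g$label[g$gene_id == "gA"], "MaD")
  # conflicting promoter labels -> ND
  expect_equal(g$label[g$gene_id == "gB"], "ND")
  # no promoter peak at any stage -> unmarked (distal peak ignored)
  expect_equal(g$label[g$gene_id == "gC"], "unmarked")

  # perturbing distal peaks changes nothing
  peaks2 <- peaks
  peaks2$label[4] <- "MaD"
  peaks2$start[4] <- 300000L; peaks2$end[4] <- 300500L
  expect_equal(classify_gene_h3k4me3(tss, peaks2, 250L)$label, g$label)
})

test_that("gene-level H3K27me3: MaD dominates, ZyD needs absence of MaD", {
  tss <- data.frame(gene_id = c("g1", "g2", "g3"), scaffold = "scaffold_1",
                    tss = c(10000L, 50000L, 90000L), strand = "+")
  peaks <- data.frame(
    scaffold = "scaffold_1",
    start = c(8000L, 11000L, 48000L, 88000L),
    end = c(8500L, 11500L, 48500L, 88500L),
    label = c("MaD", "ZyD", "ZyD", "ND"),
    stringsAsFactors = FALSE
  )
  g <- classify_gene_h3k27me3(tss, peaks, flank = 2500L)
  expect_equal(g$label, c("MaD", "ZyD", "ND"))
})

test_that("regulatory domains follow basal-plus-extension rules", {
  lens <- c(scaffold_1 = 1000000L)
  one <- data.frame(gene_id = "g1", scaffold = "scaffold_1",
                    tss = 500000L, strand = "+")
  d <- great_regions(one, lens)
  expect_equal(d$basal_start, 495000L)
  expect_equal(d$basal_end, 501000L)
  expect_equal(d$start, 0L)        # 1 Mb cap spans the whole scaffold
  expect_equal(d$end, 1000000L)

  # neighbouring genes stop each other's extension at the basal boundary
  two <- data.frame(gene_id = c("gL", "gR"), scaffold = "scaffold_1",
                    tss = c(400000L, 430000L), strand = c("+", "+"))
  d2 <- great_regions(two, lens)
  expect_equal(d2$end[1], d2$basal_start[2])
  expect_equal(d2$start[2], d2$basal_end[1])

  # minus strand flips the basal asymmetry
  mn <- data.frame(gene_id = "gm", scaffold = "scaffold_1",
                   tss = 500000L, strand = "-")
  dm <- great_regions(mn, lens)
  expect_equal(dm$basal_start, 499000L)
  expect_equal(dm$basal_end, 505000L)

  # scaffold edge clips
  edge <- data.frame(gene_id = "ge", scaffold = "scaffold_1",
                     tss = 2000L, strand = "+")
  expect_equal(great_regions(edge, lens)$start, 0L)
  expect_error(great_regions(rbind(one, one), lens), "duplicate")
})

test_that("domain peak counts equal the brute-force double loop", {
  set.seed(13)
  lens <- c(scaffold_1 = 2000000L)
  tss <- data.frame(gene_id = sprintf("g%02d", 1:15), scaffold = "scaffold_1",
                    tss = sort(sample.int(2000000L, 15)),
                    strand = sample(c("+", "-"), 15, TRUE))
  dom <- great_regions(tss, lens)
  pk <- data.frame(scaffold = "scaffold_1",
                   start = sample.int(1999000L, 60))
  pk$end <- pk$start + 500L
  pk$label <- sample(c("MaD", "ZyD", "ND"), 60, TRUE)
  got <- count_peaks_in_domains(dom, pk)
  for (i in seq_len(nrow(dom))) {
    for (lb in c("MaD", "ZyD", "ND")) {
      manual <- sum(pk$label == lb & pk$start < dom$end[i] &
                      pk$end > dom$start[i])
      expect_equal(got[[paste0("n_", lb)]][i], manual)
    }
  }
})

test_that("expression grouping takes the maximum stage, earlier on ties", {
  ex <- rbind(
    gA = c(oocyte = 0, blastula = 1, gastrula = 5, neurula = 2, tailbud = 0),
    gB = c(oocyte = 9, blastula = 0, gastrula = 1, neurula = 0, tailbud = 0),
    gC = c(oocyte = 0, blastula = 0, gastrula = 3, neurula = 3, tailbud = 1),
    gD = c(oocyte = 0, blastula = 0, gastrula = 0, neurula = 0, tailbud = 0)
  )
  groups <- c(blastula = "blastula", gastrula = "gastrula",
              neurula = "neurula", tailbud = "tailbud")
  g <- suppressMessages(
    group_genes_by_expression(ex, "oocyte", groups, maternal_threshold = 1))
  expect_equal(g$group[g$gene_id == "gA"], "gastrula")
  expect_false("gB" %in% g$gene_id)   # maternal expression above threshold
  expect_equal(g$group[g$gene_id == "gC"], "gastrula")  # tie -> earlier
  expect_false("gD" %in% g$gene_id)   # all-zero excluded
})

test_that("gene-set summaries count labels and warn on unknown ids", {
  labs <- data.frame(gene_id = sprintf("g%d", 1:8),
                     label = c(rep("MaD", 7), "ZyD"))
  s <- summarize_gene_set(sprintf("g%d", 1:8), labs)
  expect_equal(as.integer(s$counts[c("MaD", "ZyD", "ND")]), c(7L, 1L, 0L))
  expect_warning(summarize_gene_set(c("g1", "nope"), labs), "unknown")
  empty <- summarize_gene_set(character(0), labs)
  expect_equal(length(empty$counts), 0)
})
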
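test_that("stitching merges chains by gap, including the boundary", {
  pk <- data.frame(scaffold = "scaffold_1",
                   start = c(0L, 10000L, 30000L),
                   end = c(500L, 10500L, 30500L),
                   signal = c(1, 1, 1))
  st <- stitch_peaks(pk, 12500L)
  expect_equal(st$start, c(0L, 30000L))
  expect_equal(st$end, c(10500L, 30500L))
  expect_equal(st$n_members, c(2L, 1L))

  # gap exactly 12,500 bp is stitched (<= rule)
  pk2 <- data.frame(scaffold = "scaffold_1", start = c(0L, 13000L),
                    end = c(500L, 13500L), signal = c(1, 1))
  expect_equal(nrow(stitch_peaks(pk2, 12500L)), 1)
  # one bp more is not
  pk3 <- data.frame(scaffold = "scaffold_1", start = c(0L, 13001L),
                    end = c(500L, 13501L), signal = c(1, 1))
  expect_equal(nrow(stitch_peaks(pk3, 12500L)), 2)
})

test_that("stitching equals brute-force chaining, idempotent, order-free", {
  set.seed(17)
  n <- 1000
  starts <- sort(sample.int(5e6, n))
  pk <- data.frame(scaffold = "scaffold_1", start = starts,
                   end = starts + sample(200:800, n, TRUE),
                   signal = rexp(n))
  pk <- pk[pk$end <= 5e6, ]
  st <- stitch_peaks(pk, 12500L)
  oracle <- stitch_oracle(pk$start, pk$end, 12500L)
  expect_equal(st$start, unname(oracle[, "start"]))
  expect_equal(st$end, unname(oracle[, "end"]))
  expect_equal(st$n_members, unname(as.integer(oracle[, "n_members"])))

  # order independence
  sh <- pk[sample.int(nrow(pk)), ]
  st2 <- stitch_peaks(sh, 12500L)
  expect_equal(st2$start, st$start)
  expect_equal(st2$signal, st$signal)

  # idempotence: stitching the stitched regions changes nothing
  st3 <- stitch_peaks(st, 12500L)
  expect_equal(st3$start, st$start)
  expect_equal(st3$end, st$end)
})

test_that("elbow cutoff sits at scaled rank 0.5 on a quadratic profile", {
  n <- 101
  x <- seq(0, 1, length.out = n)
  ec <- elbow_cutoff(x^2)
  expect_lt(abs(ec$cutoff_rank_scaled - 0.5), 1 / (n - 1) + 1e-12)
  expect_equal(sum(ec$is_ec), sum(x^2 > ec$threshold))

  expect_warning(res <- elbow_cutoff(rep(3, 10)), "all signals equal")
  expect_false(any(res$is_ec))
  # linear profile is degenerate: nothing flagged
  lin <- elbow_cutoff(seq(0, 1, length.out = 50))
  expect_false(any(lin$is_ec))
  expect_true(is.na(lin$cutoff_rank_scaled))
  expect_error(elbow_cutoff(c(1, 2)), "at least 3")
})

test_that("two-population signals put planted clusters above the cutoff", {
  set.seed(23)
  hits <- replicate(20, {
    sig <- c(rexp(200, 1), rexp(20, 1) + 20)
    ec <- elbow_cutoff(sig)
    mean(ec$is_ec[201:220])
  })
  expect_gte(mean(hits), 0.95)
})

test_that("catalog coverage is measured against the merged total region", {
  pk <- data.frame(
    stage = rep(c("9", "30"), c(2, 4)),
    scaffold = "scaffold_1",
    start = c(0L, 5000L, 0L, 5000L, 100000L, 104000L),
    end = c(1000L, 6000L, 1000L, 6000L, 101000L, 105000L),
    signal = c(50, 50, 50, 50, 60, 60)
  )
  # add low singletons so the elbow has a background population
  bg <- data.frame(stage = rep(c("9", "30"), each = 30),
                   scaffold = "scaffold_1",
                   start = seq(1000000L, by = 50000L, length.out = 60))
  bg$end <- bg$start + 500L
  bg$signal <- 0.01
  cat <- build_catalog(rbind(pk, bg), 12500L)
  expect_equal(nrow(cat$total), 2)
  # stage 9 covers only the first cluster footprint of the total region
  total_bp <- sum(cat$total$end - cat$total$start)
  expect_equal(unname(cat$stage_coverage["9"]), 6000 / total_bp)
  expect_equal(unname(cat$stage_coverage["30"]), 1)
  expect_true(all(cat$ec_stage_coverage <= 1))

  # single stage: total region equals that stage's clusters, coverage 1
  single <- build_catalog(rbind(pk, bg)[rbind(pk, bg)$stage == "9", ], 12500L)
  expect_equal(unname(single$stage_coverage), 1)
})

test_that("seeding records earliest-stage peak labels per cluster", {
  pk <- data.frame(stage = "9", scaffold = "scaffold_1",
                   start = c(100L, 200000L), end = c(600L, 200500L),
                   signal = 50, label = c("MaD", "ZyD"))
  catalog <- list(total = data.frame(
    scaffold = "scaffold_1", start = c(0L, 199000L, 400000L),
    end = c(10000L, 210000L, 401000L),
    ec_id = c("EC_0001", "EC_0002", "EC_0003")))
  sd <- seeding_analysis(catalog, pk)
  expect_equal(sd$seed_class, c("MaD", "ZyD", "unseeded"))
  expect_equal(sd$n_seeds, c(1L, 1L, 0L))
})

test_that("EC enrichment reproduces the exact hypergeometric example", {
  # 20 peaks, 5 in ECs, all 5 ZyD peaks in ECs: p = 1/choose(20,5)
  peaks <- data.frame(
    scaffold = "scaffold_1",
    start = c(seq(0L, by = 1000L, length.out = 5),
              seq(100000L, by = 1000L, length.out = 15)),
    label = c(rep("ZyD", 5), rep("MaD", 15))
  )
  peaks$end <- peaks$start + 500L
  catalog <- list(total = data.frame(scaffold = "scaffold_1", start = 0L,
                                     end = 6000L, ec_id = "EC_0001"))
  fr <- label_fraction_in_ecs(peaks, catalog)
  expect_equal(fr$fraction[fr$label == "ZyD"], 1)
  expect_equal(fr$p_over[fr$label == "ZyD"], 1 / 15504, tolerance = 1e-12)
  # proportionally distributed label is not enriched
  expect_gte(fr$p_over[fr$label == "MaD"], 0.5)

  # no peaks in ECs at all: fraction 0, over-representation p = 1
  far <- catalog
  far$total$start <- 5e6; far$total$end <- 5e6 + 100
  fr0 <- label_fraction_in_ecs(peaks, far)
  expect_equal(fr0$fraction, c(0, 0))
  expect_equal(fr0$p_over, c(1, 1))
})

test_that("hypergeometric tails match enumeration for all populations <= 30", {
  max_err <- 0
  for (N in 1:30) {
    for (K in 0:N) {
      for (n in 0:N) {
        for (k in 0:min(K, n)) {
          e1 <- abs(hypergeom_tail(k, K, N, n, TRUE) -
                      hyper_oracle(k, K, N, n, TRUE))
          e2 <- abs(hypergeom_tail(k, K, N, n, FALSE) -
                      hyper_oracle(k, K, N, n, FALSE))
          max_err <- max(max_err, e1, e2)
        }
      }
    }
  }
  expect_lt(max_err, 1e-12)
})

test_that("EC composition is union coverage, not double-counted", {
  catalog <- list(total = data.frame(scaffold = "scaffold_1", start = 0L,
                                     end = 1000L, ec_id = "EC_0001"))
  # two overlapping ZyD peaks tile the whole EC
  pk <- data.frame(scaffold = "scaffold_1", start = c(0L, 400L, 0L),
                   end = c(600L, 1000L, 300L),
                   label = c("ZyD", "ZyD", "MaD"))
  comp <- ec_madzyd_composition(catalog, pk)
  expect_equal(comp$per_ec$frac_ZyD, 1)
  expect_equal(comp$per_ec$frac_MaD, 0.3)
  expect_equal(unname(comp$quartiles["ZyD", "q50"]), 1)
})

test_that("nearest gene reports distance 0 inside and ties outside", {
  tss <- data.frame(gene_id = c("near", "far", "tieA", "tieB"),
                    scaffold = c("scaffold_1", "scaffold_1",
                                 "scaffold_2", "scaffold_2"),
                    tss = c(5000L, 20000L, 900L, 3099L),
                    strand = "+")
  ecs <- data.frame(scaffold = c("scaffold_1", "scaffold_2", "scaffold_3"),
                    start = c(4000L, 1900L, 0L),
                    end = c(6000L, 2100L, 100L),
                    ec_id = c("EC_0001", "EC_0002", "EC_0003"))
  ng <- nearest_gene(ecs, tss)
  expect_equal(ng$gene_id[1], "near")
  expect_equal(ng$distance[1], 0)
  expect_equal(ng$gene_id[2], "tieA,tieB")  # both at 1000 bp
  expect_true(is.na(ng$gene_id[3]))         # no TSS on that scaffold
})
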
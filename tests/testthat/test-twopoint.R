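test_that("Kosambi conversions match closed forms and invert each other", {
  expect_equal(kosambi_cm(0), 0)
  expect_equal(kosambi_cm(0.25), 25 * log(3))
  expect_equal(kosambi_rf(10), 0.5 * tanh(0.2))
  expect_error(kosambi_cm(0.5), "0.5")
  theta <- seq(0, 0.49, by = 0.005)
  expect_true(all(abs(kosambi_rf(kosambi_cm(theta)) - theta) < 1e-10))
})

test_that("testcross rf and LOD match the likelihood-ratio formula", {
  mk <- function(R, n) {
    a <- rep("ll", n)
    b <- a
    b[seq_len(R)] <- "lm"
    list(a = a, b = b)
  }
  # perfect linkage: boundary LOD = n log10 2
  z <- rf_testcross(mk(0, 100)$a, mk(0, 100)$b)
  expect_equal(z$rf, 0)
  expect_equal(z$lod, 100 * log10(2))
  # independent evaluation of the likelihood-ratio formula
  z10 <- rf_testcross(mk(10, 100)$a, mk(10, 100)$b)
  oracle <- 100 * log10(2) + 10 * log10(0.1) + 90 * log10(0.9)
  expect_equal(z10$rf, 0.1)
  expect_equal(z10$lod, oracle)
  expect_equal(z10$lod, 15.9848, tolerance = 1e-4)
  # independence
  z50 <- rf_testcross(mk(50, 100)$a, mk(50, 100)$b)
  expect_equal(z50$rf, 0.5)
  expect_equal(z50$lod, 0)
  # phase handling: complementing one vector flips phase, not rf
  cmpl <- ifelse(mk(10, 100)$b == "lm", "ll", "lm")
  zr <- rf_testcross(mk(10, 100)$a, cmpl)
  expect_equal(zr$rf, 0.1)
  expect_equal(zr$phase, "repulsion")
  expect_error(rf_testcross(rep("--", 5), rep("ll", 5)), "pairwise")
})

test_that("F2 EM estimator agrees with a grid-search oracle and recovers truth", {
  # identical call vectors cosegregate completely
  x <- rep(c("A", "H", "B"), times = c(25, 50, 25))
  expect_equal(rf_f2(x, x)$rf, 0, tolerance = 1e-6)

  # EM optimum equals an independently coded grid-search MLE
  set.seed(91)
  lv <- c("A", "H", "B")
  for (rep in 1:20) {
    r <- runif(1, 0.02, 0.45)
    phase_flip <- runif(1) < 0.5
    p <- oracle_f2_probs(if (phase_flip) 1 - r else r)
    n <- 200
    cells <- sample(9, n, replace = TRUE, prob = as.vector(p))
    tab <- matrix(tabulate(cells, 9), 3, 3)
    calls_a <- rep(lv[(cells - 1) %% 3 + 1])
    calls_b <- rep(lv[(cells - 1) %/% 3 + 1])
    z <- rf_f2(calls_a, calls_b)
    expect_lt(abs(z$rf - oracle_f2_grid(tab)), 1e-4)
  }

  # parameter recovery at n = 10,000, true theta = 0.1
  d <- -50 * log(1 - 2 * 0.1)  # Haldane distance giving rf 0.1
  tm <- line_map(c(0, d), length_cM = ceiling(d))
  gm <- sim_f2(tm, 10000, seed = 92)
  z <- rf_f2(gm$calls[1, ], gm$calls[2, ])
  expect_lt(abs(z$rf - 0.1), 0.01)

  expect_error(rf_f2(rep("A", 50), rep("A", 50)), "degenerate")
})

test_that("grouping by LOD threshold recovers linkage groups", {
  tm <- true_map(
    data.frame(lg = c("LG1", "LG2"), length_cM = c(50, 50)),
    data.frame(marker_id = sprintf("M%02d", 1:12),
               lg = rep(c("LG1", "LG2"), each = 6),
               pos_cM = rep(seq(0, 50, by = 10), 2)))
  cd <- cross_design("F2_SELF", list(parent = f2_parent(tm)), 150,
                     seed = 101)
  gm <- simulate_cross(cd, tm, 0, 0)
  lk <- pairwise_linkage(gm)
  gr <- group_markers(lk, lod_min = 3)
  expect_length(gr, 2)
  expect_setequal(gr[[1]], sprintf("M%02d", 1:6))
  expect_setequal(gr[[2]], sprintf("M%02d", 7:12))
  # an infinite threshold isolates every marker
  gr_inf <- group_markers(lk, lod_min = Inf)
  expect_length(gr_inf, 12)
})

test_that("ordering recovers the simulated marker order and is input-order invariant", {
  tm <- line_map(seq(0, 90, by = 10))
  gm <- sim_f2(tm, 500, seed = 111)
  lk <- pairwise_linkage(gm)
  truth <- tm$markers$marker_id
  om <- order_markers(truth, lk)
  expect_true(identical(om$marker_id, truth) ||
                identical(om$marker_id, rev(truth)))
  # permutation invariance
  set.seed(1)
  om2 <- order_markers(sample(truth), lk)
  expect_identical(om2$marker_id, om$marker_id)
  # estimated length within 10% of the Kosambi truth
  true_len <- sum(kosambi_cm(haldane_rf(diff(seq(0, 90, by = 10)))))
  expect_lt(abs(max(om$pos_cM) - true_len) / true_len, 0.1)
  # two markers: positions 0 and d
  om3 <- order_markers(truth[1:2], lk)
  expect_equal(om3$pos_cM[1], 0)
  expect_gt(om3$pos_cM[2], 0)
})

test_that("accessory markers attach to the strongest-LOD framework marker", {
  fw <- data.frame(marker_id = c("F1", "F2", "F3"), pos_cM = c(0, 10, 20))
  lk <- data.frame(marker_a = c("ACC", "ACC", "ACC"),
                   marker_b = c("F1", "F2", "F3"),
                   rf = c(0.30, 0.01, 0.25), lod = c(4, 20, 5),
                   n_informative = 100, phase = "coupling")
  pl <- place_accessory(fw, "ACC", lk)
  expect_equal(pl$nearest_framework, "F2")
  expect_equal(pl$attach_dist_cM, kosambi_cm(0.01))
  # tie on LOD resolved toward the smaller distance
  lk$lod <- c(20, 20, 5)
  lk$rf <- c(0.05, 0.02, 0.25)
  expect_message(pl2 <- place_accessory(fw, "ACC", lk), "tie")
  expect_equal(pl2$nearest_framework, "F2")
  # unlinked marker stays unplaced
  lk$lod <- c(1, 2, 1)
  expect_message(pl3 <- place_accessory(fw, "ACC", lk), "unplaced")
  expect_null(pl3)
})

test_that("same-contig comparisons measure the genotyping error rate", {
  # duplicated marker rows: zero events whatever n
  tm <- line_map(c(10, 10), length_cM = 20, contig = c("ctg1", "ctg1"))
  gm <- sim_f2(tm, 200, seed = 121)
  cc <- contig_consistency(gm)
  expect_equal(cc$n_events, 0)
  expect_equal(cc$error_rate_pct, 0)
  expect_equal(cc$n_comparisons, 200)
  # inject known discordances
  gm2 <- gm
  gm2$calls[2, 1:5] <- ifelse(gm2$calls[2, 1:5] == "A", "H", "A")
  cc2 <- contig_consistency(gm2)
  expect_equal(cc2$n_events, 5)
  expect_equal(cc2$error_rate_pct, 100 * 5 / 200)
  # allele re-orientation: swapping A/B labels of one marker is no error
  gm3 <- gm
  swap <- c(A = "B", H = "H", B = "A")
  gm3$calls[2, ] <- swap[gm3$calls[2, ]]
  cc3 <- contig_consistency(gm3)
  expect_equal(cc3$n_events, 0)
  expect_error(contig_consistency(sim_f2(line_map(c(0, 10)), 50, seed = 1)),
               "contig")
})

test_that("build_map assembles framework and accessory markers on a CP family", {
  tm <- line_map(seq(0, 60, by = 6), length_cM = 60)
  gm <- sim_cp(tm, 300, seed = 131, prop = c(mat = 0.7, pat = 0, both = 0.3))
  mp <- build_map(gm, parent = "mother", lod_min = 3)
  expect_s3_class(mp, "genetic_map")
  expect_true(all(c("framework", "accessory") %in% mp$role))
  # framework order matches simulated order up to reversal
  fw <- mp$marker_id[mp$role == "framework"]
  truth <- gm$markers$marker_id[gm$markers$seg_type == "lmxll"]
  expect_true(identical(fw, truth) || identical(fw, rev(truth)))
  # accessory markers sit near their true neighbours
  acc <- mp[mp$role == "accessory", ]
  for (i in seq_len(nrow(acc))) {
    true_pos <- gm$markers$pos_cM[gm$markers$marker_id == acc$marker_id[i]]
    fw_true <- gm$markers$pos_cM[gm$markers$marker_id == acc$nearest_framework[i]]
    expect_lt(abs(true_pos - fw_true), 15)
  }
})
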
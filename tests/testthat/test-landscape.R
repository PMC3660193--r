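test_that("plug-in bandwidth matches an independent Sheather-Jones implementation", {
  set.seed(901)
  x <- runif(200, 0, 100)
  h <- select_bandwidth(x)
  expect_lt(abs(h - oracle_sj_dpi(x)) / oracle_sj_dpi(x), 0.2)
  # scale equivariance
  expect_equal(select_bandwidth(2 * x), 2 * select_bandwidth(x),
               tolerance = 1e-6)
  # degenerate and small inputs fall back with a warning
  expect_warning(h0 <- select_bandwidth(rep(10, 8)), "falling back")
  expect_gte(h0, 1)
  expect_warning(h4 <- select_bandwidth(c(1, 2, 3, 4)), "falling back")
  expect_gt(h4, 0)
})

test_that("window counts agree with a brute-force recount", {
  # all markers in the first window
  w <- window_counts(runif(10, 0, 0.99), lg_length = 50, h = 5)
  expect_equal(w$count[1], 10)
  # regular 1-cM grid, h = 10: interior windows hold exactly 10 markers
  pos <- seq(0, 99, by = 1)
  w2 <- window_counts(pos, 100, h = 10, step = 1)
  expect_true(all(w2$count == 10))
  # brute-force recount on random positions
  set.seed(902)
  pos3 <- runif(300, 0, 120)
  w3 <- window_counts(pos3, 120, h = 7, step = 1)
  brute <- vapply(w3$start, function(s)
    sum(pos3 >= s & pos3 < s + 7), integer(1))
  expect_identical(w3$count, brute)
  # each interior marker appears in ceiling(h/step) windows
  hits <- vapply(pos3[pos3 > 7 & pos3 < 113 - 7], function(p)
    sum(w3$start <= p & p < w3$start + 7), integer(1))
  expect_true(all(hits %in% c(6, 7, 8)))
  # oversized bandwidth collapses to a single window with a warning
  expect_warning(w4 <- window_counts(pos, 100, h = 150), "single")
  expect_equal(nrow(w4), 1)
  expect_equal(w4$count, 100)
})

test_that("Poisson thresholds stay silent on null maps and find planted signal", {
  # null: i.i.d. Poisson(4) counts, no thresholds in almost all seeds
  silent <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    th <- poisson_thresholds(rpois(5000, 4), alpha = 0.01)
    is.na(th$k_cold) && is.na(th$k_hot)
  }, logical(1))
  expect_gte(sum(silent), 18)
  # planted dense windows: coldspot threshold found at or below 15
  set.seed(1021)
  th2 <- poisson_thresholds(c(rpois(5000, 4), rep(15, 50)), alpha = 0.01)
  expect_false(is.na(th2$k_cold))
  expect_lte(th2$k_cold, 15)
  # planted empty windows: hotspot threshold found
  set.seed(1022)
  th3 <- poisson_thresholds(c(rpois(5000, 4), rep(0, 80)), alpha = 0.01)
  expect_false(is.na(th3$k_hot))
  expect_gte(th3$k_hot, 0)
  expect_error(poisson_thresholds(rpois(10, 4)), "too few")
})

test_that("interval calling merges threshold-passing runs and nothing else", {
  win <- data.frame(lg = "LG1", start = 0:9,
                    count = c(2, 9, 2, 2, 9, 9, 2, 0, 0, 2), h = 3)
  iv <- call_intervals(win, k_cold = 9, k_hot = 0)
  cold <- iv[iv$kind == "coldspot", ]
  hot <- iv[iv$kind == "hotspot", ]
  # two coldspot runs: the singleton at start 1 and the pair at 4-5
  expect_equal(nrow(cold), 2)
  expect_equal(cold$start, c(1, 4))
  expect_equal(cold$end, c(1 + 3, 5 + 3))
  expect_equal(cold$peak, c(9, 9))
  # one hotspot run at 7-8
  expect_equal(nrow(hot), 1)
  expect_equal(hot$start, 7)
  expect_equal(hot$end, 8 + 3)
  # disabled thresholds yield nothing
  expect_equal(nrow(call_intervals(win, NA, NA)), 0)
})

test_that("cross-map matching labels shared and specific features", {
  mk <- function(ids, pos) fixture_map("LG1", ids, pos)
  mapA <- mk(paste0("A", 1:11), seq(0, 100, by = 10))
  mapB <- mapA  # same anchors
  featA <- data.frame(kind = "hotspot", lg = "LG1", start = 20, end = 30,
                      peak = 0)
  featB <- data.frame(kind = "hotspot", lg = "LG1", start = 25, end = 35,
                      peak = 0)
  m1 <- match_intervals(list(A = featA, B = featB),
                        list(A = mapA, B = mapB))
  expect_equal(m1$venn$shared_two, 1)
  expect_equal(m1$venn$specific, 0)
  # disjoint features stay specific
  featC <- data.frame(kind = "hotspot", lg = "LG1", start = 60, end = 70,
                      peak = 0)
  m2 <- match_intervals(list(A = featA, B = featC),
                        list(A = mapA, B = mapB))
  expect_equal(m2$venn$specific, 2)
  expect_equal(m2$venn$shared_two, 0)
  # kinds never match each other
  featD <- transform(featB, kind = "coldspot")
  m3 <- match_intervals(list(A = featA, B = featD),
                        list(A = mapA, B = mapB))
  expect_true(all(m3$venn$shared_two == 0))
  # three maps, one hotspot common to all plus map-specific ones
  featB2 <- rbind(featB, featC)
  featE <- data.frame(kind = "hotspot", lg = "LG1",
                      start = c(22, 80), end = c(32, 90), peak = 0)
  m4 <- match_intervals(list(A = featA, B = featB2, C = featE),
                        list(A = mapA, B = mapB, C = mapA))
  expect_equal(m4$venn$shared_all[m4$venn$kind == "hotspot"], 1)
})

test_that("Jaccard similarity counts matched feature pairs over the union", {
  mapA <- fixture_map("LG1", paste0("A", 1:11), seq(0, 100, by = 10))
  f <- function(starts) data.frame(kind = rep("hotspot", length(starts)),
                                   lg = rep("LG1", length(starts)),
                                   start = starts, end = starts + 5,
                                   peak = rep(0, length(starts)))
  expect_equal(jaccard_features(f(c(0, 30, 60)), f(c(0, 30, 60)),
                                mapA, mapA), 1)
  expect_equal(jaccard_features(f(c(0, 30)), f(c(60, 90)), mapA, mapA), 0)
  # 2 shared of 3 and 4: union 5, index 0.4
  expect_equal(jaccard_features(f(c(0, 30, 60)),
                                f(c(1, 31, 80, 90)), mapA, mapA), 0.4)
  expect_message(j <- jaccard_features(f(numeric(0)), f(numeric(0)),
                                       mapA, mapA), "undefined")
  expect_true(is.na(j))
})

test_that("feature means per chromosome match the printed arithmetic", {
  expect_equal(summarize_features(c(71, 62, 69), 12), 5.6)
  expect_equal(summarize_features(c(0, 0, 0), 12), 0)
  expect_equal(summarize_features(36, 12), 3)
  expect_error(summarize_features(c(1, 2), 0), "positive")
})

test_that("false-feature rate on homogeneous maps stays at or below alpha", {
  set.seed(1100)
  called <- 0; total <- 0
  for (s in 1:200) {
    counts <- rpois(400, 5)
    th <- poisson_thresholds(counts, alpha = 0.01)
    total <- total + length(counts)
    if (!is.na(th$k_cold)) called <- called + sum(counts >= th$k_cold)
    if (!is.na(th$k_hot)) called <- called + sum(counts <= th$k_hot)
  }
  expect_lte(called / total, 0.01)
})
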
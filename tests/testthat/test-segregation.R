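test_that("chi-square ratio test matches direct computation and flags at alpha", {
  z <- chi2_ratio_test(c(25, 50, 25), c(1, 2, 1))
  expect_equal(z$chi2, 0)
  expect_equal(z$p_value, 1)
  expect_false(z$distorted)
  expect_equal(chi2_ratio_test(c(50, 50), c(1, 1))$chi2, 0)

  # missing homozygote class: oracle = direct sum((O-E)^2/E)
  obs <- c(23, 46, 0)
  E <- c(17.25, 34.5, 17.25)
  oracle_chi2 <- sum((obs - E)^2 / E)
  z2 <- suppressWarnings(chi2_ratio_test(obs, c(1, 2, 1)))
  expect_equal(z2$chi2, oracle_chi2)
  expect_equal(z2$df, 2)
  expect_true(z2$distorted)
  # independent cross-check against stats::chisq.test
  ref <- suppressWarnings(stats::chisq.test(obs, p = c(0.25, 0.5, 0.25)))
  expect_equal(z2$chi2, unname(ref$statistic))
  expect_equal(z2$p_value, ref$p.value)

  expect_error(chi2_ratio_test(c(0, 0, 0), c(1, 2, 1)), "zero")
  expect_error(chi2_ratio_test(c(10, 10), c(1, 2, 1)), "ratio")
  expect_warning(chi2_ratio_test(c(3, 5, 2), c(1, 2, 1)), "below 5")
})

test_that("SDR detection clusters distorted markers and separates singletons", {
  # 4 adjacent distorted markers within 5 cM form one region
  mp <- fixture_map("LG1", sprintf("M%02d", 1:8),
                    c(0, 1.5, 3, 4.5, 20, 30, 40, 50))
  seg <- data.frame(marker_id = sprintf("M%02d", 1:8),
                    distorted = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
                                  FALSE, FALSE))
  sd <- detect_sdr(mp, seg, min_cluster = 3, max_gap_cM = 10)
  expect_equal(nrow(sd$regions), 1)
  expect_equal(sd$regions$n_distorted, 4)
  expect_equal(sd$regions$start_cM, 0)
  expect_equal(sd$regions$end_cM, 4.5)

  # 27 distorted markers, 25 clustered at three map neighbourhoods:
  # three regions plus two isolated distorted markers
  pos <- c(seq(0, 9, by = 1),          # 10 markers cluster 1 (LG10)
           seq(40, 47, by = 1),        # 8 markers cluster 2 (LG10)
           seq(10, 16, by = 1),        # 7 markers cluster 3 (LG2)
           60, 80)                     # 2 singletons elsewhere
  lg <- c(rep("LG10", 18), rep("LG2", 7), "LG5", "LG7")
  ids <- sprintf("D%02d", seq_along(pos))
  extra <- data.frame(lg = c("LG10", "LG2", "LG5", "LG7"),
                      marker_id = paste0("N", 1:4),
                      pos_cM = c(100, 100, 100, 100))
  mp2 <- fixture_map(c(lg, extra$lg), c(ids, extra$marker_id),
                     c(pos, extra$pos_cM))
  seg2 <- data.frame(marker_id = c(ids, extra$marker_id),
                     distorted = c(rep(TRUE, 27), rep(FALSE, 4)))
  sd2 <- detect_sdr(mp2, seg2, min_cluster = 3, max_gap_cM = 10)
  expect_equal(nrow(sd2$regions), 3)
  expect_equal(sum(sd2$regions$n_distorted), 25)
  expect_equal(nrow(sd2$singletons), 2)

  # tested non-distorted marker breaks a run even inside the gap limit
  mp3 <- fixture_map("LG1", c("A1", "A2", "A3", "A4"), c(0, 2, 4, 6))
  seg3 <- data.frame(marker_id = c("A1", "A2", "A3", "A4"),
                     distorted = c(TRUE, FALSE, TRUE, TRUE))
  sd3 <- detect_sdr(mp3, seg3, min_cluster = 3)
  expect_equal(nrow(sd3$regions), 0)
  expect_equal(nrow(sd3$singletons), 3)

  # untested markers are skipped without breaking, within the gap limit
  seg4 <- data.frame(marker_id = c("A1", "A3", "A4"),
                     distorted = c(TRUE, TRUE, TRUE))
  sd4 <- detect_sdr(mp3, seg4, min_cluster = 3)
  expect_equal(nrow(sd4$regions), 1)

  # no distorted markers: empty result
  seg5 <- data.frame(marker_id = c("A1", "A2"), distorted = c(FALSE, FALSE))
  expect_equal(nrow(detect_sdr(mp3, seg5)$regions), 0)
  expect_error(detect_sdr(mp3, data.frame(marker_id = "ZZ",
                                          distorted = TRUE)),
               "absent")
})

test_that("inbred/outbred contrast retains only F2-specific SDRs", {
  mp_f2 <- fixture_map("LG2", c("S1", "S2", "S3", "S4", "K1", "K2"),
                       c(10, 12, 14, 16, 0, 40))
  mp_g2 <- fixture_map("LG2", c("G1", "G2", "K1", "K2"),
                       c(5, 15, 0, 40))
  sdr <- data.frame(lg = "LG2", start_cM = 10, end_cM = 16,
                    n_distorted = 4, members = "S1,S2,S3,S4",
                    status = "candidate", stage = "undetermined",
                    origin = NA_character_, stringsAsFactors = FALSE)
  seg_clean <- data.frame(marker_id = c("G1", "G2"),
                          distorted = c(FALSE, FALSE))
  seg_hit <- data.frame(marker_id = c("G1", "G2"),
                        distorted = c(FALSE, TRUE))
  # clean outbred maps: candidate retained
  out <- contrast_pedigrees(sdr, mp_f2, mp_g2, mp_g2, seg_clean, seg_clean)
  expect_equal(nrow(out), 1)
  # distorted G2 marker inside the projected interval: excluded
  out2 <- contrast_pedigrees(sdr, mp_f2, mp_g2, mp_g2, seg_hit, seg_clean)
  expect_equal(nrow(out2), 0)
  # empty candidate list passes through
  expect_equal(nrow(contrast_pedigrees(sdr[0, ], mp_f2, mp_g2, mp_g2,
                                       seg_clean, seg_clean)), 0)
  # no shared anchors: explicit error
  mp_far <- fixture_map("LG9", c("X1", "X2"), c(0, 10))
  expect_error(contrast_pedigrees(sdr, mp_f2, mp_far, mp_far,
                                  seg_clean, seg_clean), "anchor")
})

test_that("a distortion source in one outbred parent is never called an inbreeding candidate", {
  # distorted markers on the G2F map at the same projected location
  mp_f2 <- fixture_map("LG1", c("A1", "A2", "A3", "C1", "C2"),
                       c(10, 12, 14, 0, 30))
  mp_g2f <- fixture_map("LG1", c("B1", "C1", "C2"), c(12, 0, 30))
  mp_g2m <- fixture_map("LG1", c("D1", "C1", "C2"), c(12, 0, 30))
  sdr <- data.frame(lg = "LG1", start_cM = 10, end_cM = 14,
                    n_distorted = 3, members = "A1,A2,A3",
                    status = "candidate", stage = "undetermined",
                    origin = NA_character_, stringsAsFactors = FALSE)
  segf <- data.frame(marker_id = "B1", distorted = TRUE)
  segm <- data.frame(marker_id = "D1", distorted = FALSE)
  out <- contrast_pedigrees(sdr, mp_f2, mp_g2f, mp_g2m, segf, segm)
  expect_equal(nrow(out), 0)
})

test_that("validation in a larger cohort confirms real SDRs and rejects false positives", {
  locus <- list(lg = "LG1", pos_cM = 30,
                fitness = c("11" = 1, "12" = 1, "22" = 0))
  tm <- line_map(seq(0, 60, by = 5), viability_locus = locus)
  tm_null <- line_map(seq(0, 60, by = 5))
  cand <- data.frame(lg = "LG1", start_cM = 25, end_cM = 35,
                     n_distorted = 3, members = "M06,M07,M08",
                     status = "candidate", stage = "undetermined",
                     origin = NA_character_, stringsAsFactors = FALSE)
  # lethal locus: validated in a 380-offspring cohort
  n_val <- sum(vapply(1:10, function(s) {
    gm <- sim_f2(tm, 380, seed = 300 + s)
    validate_sdr(cand, gm, alpha = 0.01)$status == "validated"
  }, logical(1)))
  expect_gte(n_val, 9)
  # no locus: rejected in almost all cohorts
  n_rej <- sum(vapply(1:10, function(s) {
    gm <- sim_f2(tm_null, 380, seed = 400 + s)
    validate_sdr(cand, gm, alpha = 0.01)$status == "rejected"
  }, logical(1)))
  expect_gte(n_rej, 9)
  # cohort identical to discovery: status equals the discovery flag
  gm_disc <- sim_f2(tm, 380, seed = 500)
  st <- vapply(c("M06", "M07", "M08"), function(m) {
    gc <- geno_counts(gm_disc, m)
    suppressWarnings(chi2_ratio_test(gc$counts, gc$ratio, 0.01)$distorted)
  }, logical(1))
  v <- validate_sdr(cand, gm_disc, alpha = 0.01)
  expect_equal(v$status == "validated", sum(st) > length(st) / 2)
  expect_error(validate_sdr(transform(cand, members = "ZZ"), gm_disc),
               "member")
})

test_that("selection stage classification follows the parental-map evidence", {
  expect_equal(classify_stage(female = TRUE, male = FALSE, zygote = FALSE),
               "prezygotic")
  expect_equal(classify_stage(female = FALSE, male = TRUE, zygote = NA),
               "prezygotic")
  expect_equal(classify_stage(female = FALSE, male = FALSE, zygote = TRUE),
               "postzygotic")
  expect_equal(classify_stage(female = TRUE, male = TRUE, zygote = FALSE),
               "postzygotic")
  expect_equal(classify_stage(FALSE, FALSE, FALSE), "undetermined")
  expect_equal(classify_stage(NA, NA, NA), "undetermined")
})

test_that("transmission analysis names the grandparental origin of the deficit", {
  # lethality of the haplotype-2 (Corsica) homozygote class
  locus <- list(lg = "LG1", pos_cM = 10,
                fitness = c("11" = 1, "12" = 1, "22" = 0))
  tm <- line_map(c(5, 10, 15), length_cM = 30, viability_locus = locus)
  gm <- sim_f2(tm, 380, seed = 600)
  to <- transmission_origin(gm, c("M01", "M02", "M03"))
  expect_equal(to$deficit_class, "B")
  expect_equal(to$origin, "Corsica")
  # symmetric case: lethality of the haplotype-1 homozygote
  locus2 <- list(lg = "LG1", pos_cM = 10,
                 fitness = c("11" = 0, "12" = 1, "22" = 1))
  tm2 <- line_map(c(5, 10, 15), length_cM = 30, viability_locus = locus2)
  gm2 <- sim_f2(tm2, 380, seed = 601)
  to2 <- transmission_origin(gm2, c("M01", "M02", "M03"))
  expect_equal(to2$deficit_class, "A")
  expect_equal(to2$origin, "Landes")
  # neutral locus: no deficit reported in (almost) all seeds
  tm3 <- line_map(c(5, 10, 15), length_cM = 30)
  hits <- vapply(1:10, function(s) {
    gm3 <- sim_f2(tm3, 380, seed = 610 + s)
    !is.na(transmission_origin(gm3, c("M01", "M02", "M03"))$deficit_class)
  }, logical(1))
  expect_lte(sum(hits), 1)
})

test_that("null simulations flag about one percent of markers at alpha 0.01", {
  tm <- line_map(seq(0, 100, by = 10))
  flags <- unlist(lapply(1:25, function(s) {
    gm <- sim_f2(tm, 380, seed = 700 + s)
    seg <- seg_test_all(gm, alpha = 0.01)
    seg$distorted
  }))
  rate <- mean(flags)
  n <- length(flags)
  expect_lt(abs(rate - 0.01), 3 * sqrt(0.01 * 0.99 / n) + 0.002)
})
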
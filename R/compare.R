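#' Paired Wilcoxon signed rank test
#'
#' Wrapper around the signed-rank test as used for map-length and
#' pairwise-recombination comparisons: zero differences dropped, ties
#' mid-ranked, continuity-corrected normal approximation for larger
#' samples and the exact distribution for fewer than \code{exact_below}
#' informative pairs (ties force the approximation).
#'
#' @param valuesA,valuesB equal-length paired measurements.
#' @param exact_below use the exact null distribution when the number of
#'   non-zero differences is below this (default 20).
#' @return list \code{(V, p_value, n_informative)}.
#' @export
wilcoxon_paired <- function(valuesA, valuesB, exact_below = 20) {
  stopifnot(length(valuesA) == length(valuesB))
  d <- valuesA - valuesB
  ninf <- sum(d != 0)
  if (ninf == 0) {
    warning("all paired differences are zero")
    return(list(V = 0, p_value = 1, n_informative = 0L))
  }
  use_exact <- ninf < exact_below && !any(duplicated(abs(d[d != 0])))
  wt <- suppressWarnings(
    stats::wilcox.test(valuesA, valuesB, paired = TRUE,
                       exact = use_exact, correct = TRUE))
  list(V = unname(wt$statistic), p_value = wt$p.value,
       n_informative = ninf)
}

#' Z-test for a difference in recombination rate
#'
#' Tests whether the recombination fraction for the same marker pair
#' differs between two maps:
#' \deqn{Z = \frac{\theta_1 - \theta_2}
#'   {\sqrt{\theta_1(1-\theta_1)/n_1 + \theta_2(1-\theta_2)/n_2}}}
#' with a two-sided p-value from the standard normal. \code{n1}, \code{n2}
#' are the mean informative-meiosis counts of the two maps (a map-wide
#' constant in the classical usage; supply per-pair counts if preferred).
#'
#' @param theta1,theta2 recombination fractions in \code{[0, 0.5]}.
#' @param n1,n2 informative meiosis counts.
#' @return list \code{(theta1, theta2, n1, n2, Z, p_value)}; \code{Z} is
#'   \code{NA} when both fractions are 0 (undefined variance).
#' @examples
#' ztest_rf(0.3, 0.1, 69, 83)  # Z ~ 3.11
#' @export
ztest_rf <- function(theta1, theta2, n1, n2) {
  stopifnot(theta1 >= 0, theta1 <= 0.5, theta2 >= 0, theta2 <= 0.5,
            n1 >= 1, n2 >= 1)
  v <- theta1 * (1 - theta1) / n1 + theta2 * (1 - theta2) / n2
  if (v == 0) {
    warning("both recombination fractions are 0: variance undefined")
    return(list(theta1 = theta1, theta2 = theta2, n1 = n1, n2 = n2,
                Z = NA_real_, p_value = NA_real_))
  }
  z <- (theta1 - theta2) / sqrt(v)
  list(theta1 = theta1, theta2 = theta2, n1 = n1, n2 = n2, Z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' Paired within-linkage-group recombination fractions for two populations
#'
#' For all markers common to both populations and not showing segregation
#' distortion in either, computes every within-linkage-group pairwise
#' recombination fraction in each population and aligns the two lists.
#' This is the input for the genome-wide signed-rank comparison and the
#' per-pair Z-tests.
#'
#' @param gmA,gmB \code{genotype_matrix} objects.
#' @param mapA genetic map providing linkage-group assignment for the
#'   common markers (marker ids shared with both populations).
#' @param segA,segB optional [seg_test_all()] tables; distorted markers
#'   are excluded.
#' @param parentA,parentB for CP populations, which parent's meioses to use.
#' @return data.frame \code{(lg, marker_a, marker_b, rf_A, rf_B, n_A, n_B)}.
#' @export
build_paired_rf <- function(gmA, gmB, mapA, segA = NULL, segB = NULL,
                            parentA = "mother", parentB = "mother") {
  common <- intersect(gmA$markers$marker_id, gmB$markers$marker_id)
  if (!is.null(segA))
    common <- setdiff(common, segA$marker_id[segA$distorted])
  if (!is.null(segB))
    common <- setdiff(common, segB$marker_id[segB$distorted])
  common <- intersect(common, mapA$marker_id)
  if (length(common) < 2) stop("fewer than two common non-distorted markers")
  est <- function(gm, parent, m1, m2) {
    if (gm$population_type == "CP") rf_testcross(gm$calls[m1, ], gm$calls[m2, ])
    else rf_f2(gm$calls[m1, ], gm$calls[m2, ])
  }
  rows <- list()
  for (g in unique(mapA$lg[mapA$marker_id %in% common])) {
    ms <- mapA$marker_id[mapA$lg == g & mapA$marker_id %in% common]
    if (length(ms) < 2) next
    prs <- utils::combn(ms, 2)
    for (k in seq_len(ncol(prs))) {
      m1 <- prs[1, k]; m2 <- prs[2, k]
      za <- try(est(gmA, parentA, m1, m2), silent = TRUE)
      zb <- try(est(gmB, parentB, m1, m2), silent = TRUE)
      if (inherits(za, "try-error") || inherits(zb, "try-error")) next
      rows[[length(rows) + 1]] <- data.frame(
        lg = g, marker_a = m1, marker_b = m2,
        rf_A = za$rf, rf_B = zb$rf,
        n_A = za$n_informative, n_B = zb$n_informative,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no estimable common pairs")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare recombination between two maps
#'
#' Genome-wide and per-linkage-group Wilcoxon signed rank tests on paired
#' recombination fractions, plus a per-pair Z-test table.
#'
#' @param paired output of [build_paired_rf()].
#' @param n1,n2 mean informative-meiosis counts for the two maps; default
#'   the mean of the per-pair counts.
#' @param alpha significance level used to flag Z-tests.
#' @return list \code{(wilcoxon_genome, wilcoxon_per_lg, ztests)}.
#' @export
compare_recombination <- function(paired, n1 = NULL, n2 = NULL,
                                  alpha = 0.05) {
  if (is.null(n1)) n1 <- mean(paired$n_A)
  if (is.null(n2)) n2 <- mean(paired$n_B)
  wg <- wilcoxon_paired(paired$rf_A, paired$rf_B)
  per_lg <- do.call(rbind, lapply(split(paired, paired$lg), function(s) {
    w <- wilcoxon_paired(s$rf_A, s$rf_B)
    data.frame(lg = s$lg[1], n_pairs = nrow(s), V = w$V,
               p_value = w$p_value, stringsAsFactors = FALSE)
  }))
  rownames(per_lg) <- NULL
  zt <- do.call(rbind, lapply(seq_len(nrow(paired)), function(i) {
    z <- ztest_rf(min(paired$rf_A[i], 0.5), min(paired$rf_B[i], 0.5),
                  n1, n2)
    data.frame(lg = paired$lg[i], marker_a = paired$marker_a[i],
               marker_b = paired$marker_b[i], Z = z$Z,
               p_value = z$p_value,
               significant = !is.na(z$p_value) && z$p_value <= alpha,
               stringsAsFactors = FALSE)
  }))
  rownames(zt) <- NULL
  list(wilcoxon_genome = wg, wilcoxon_per_lg = per_lg, ztests = zt)
}

#' Chi-square test of marker distribution across linkage groups
#'
#' Are mapped markers spread over the linkage groups in proportion to
#' their lengths? Expected counts are \code{length_i / sum(length) * N}.
#'
#' @param map a \code{genetic_map}, or a data.frame with \code{lg} and
#'   \code{pos_cM}.
#' @return list \code{(chi2, df, p_value, table)}.
#' @export
chi2_marker_distribution <- function(map) {
  lens <- lg_spans(map)
  if (length(lens) < 2) stop("need at least two linkage groups")
  if (any(lens <= 0)) stop("zero-length linkage group")
  obs <- table(map$lg)[names(lens)]
  N <- sum(obs)
  expd <- lens / sum(lens) * N
  chi2 <- sum((obs - expd)^2 / expd)
  df <- length(lens) - 1
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df, lower.tail = FALSE),
       table = data.frame(lg = names(lens), length_cM = as.numeric(lens),
                          observed = as.integer(obs),
                          expected = as.numeric(expd), row.names = NULL))
}

#' Collinearity check between two maps
#'
#' Reports markers assigned to different linkage groups in the two maps,
#' within-linkage-group order violations (marker pairs whose relative
#' order is inverted between maps), and a per-linkage-group Spearman rank
#' correlation of positions.
#'
#' @param mapA,mapB \code{genetic_map}s sharing marker ids.
#' @return list \code{(lg_discordant, order_discordant, rank_correlation)}.
#' @export
collinearity_check <- function(mapA, mapB) {
  common <- intersect(mapA$marker_id, mapB$marker_id)
  if (length(common) < 2) stop("fewer than two common markers")
  ia <- match(common, mapA$marker_id); ib <- match(common, mapB$marker_id)
  lgA <- mapA$lg[ia]; lgB <- mapB$lg[ib]
  # linkage-group assignment: compare through the majority correspondence
  # of homologous groups rather than raw labels
  corr <- table(lgA, lgB)
  homolog <- colnames(corr)[apply(corr, 1, which.max)]
  names(homolog) <- rownames(corr)
  lg_disc <- common[lgB != homolog[lgA]]
  ord <- list(); rc <- list()
  for (g in unique(lgA)) {
    ms <- common[lgA == g & lgB == homolog[g]]
    if (length(ms) < 2) next
    pa <- mapA$pos_cM[match(ms, mapA$marker_id)]
    pb <- mapB$pos_cM[match(ms, mapB$marker_id)]
    rho <- suppressWarnings(stats::cor(pa, pb, method = "spearman"))
    if (!is.na(rho) && rho < 0) pb <- -pb  # whole-group reversal is benign
    rc[[g]] <- data.frame(lg = g, n_common = length(ms),
                          rank_correlation = abs(rho),
                          stringsAsFactors = FALSE)
    prs <- utils::combn(seq_along(ms), 2)
    for (k in seq_len(ncol(prs))) {
      i <- prs[1, k]; j <- prs[2, k]
      if (sign(pa[i] - pa[j]) * sign(pb[i] - pb[j]) < 0)
        ord[[length(ord) + 1]] <- data.frame(
          lg = g, marker_a = ms[i], marker_b = ms[j],
          stringsAsFactors = FALSE)
    }
  }
  list(lg_discordant = lg_disc,
       order_discordant = if (length(ord)) do.call(rbind, ord) else
         data.frame(lg = character(0), marker_a = character(0),
                    marker_b = character(0), stringsAsFactors = FALSE),
       rank_correlation = if (length(rc)) do.call(rbind, rc) else
         data.frame(lg = character(0), n_common = integer(0),
                    rank_correlation = numeric(0)))
}
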
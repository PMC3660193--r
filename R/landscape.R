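#' Plug-in kernel bandwidth for marker positions
#'
#' Sheather-Jones direct plug-in bandwidth for a Gaussian kernel (the
#' "fixed and robust" estimator built on the Jones-Sheather functional
#' estimates), computed per linkage group per map. With fewer than 5
#' markers, or when the plug-in pipeline fails (for example, coincident
#' positions), the function falls back to Silverman's rule and finally to
#' a fixed floor, with a warning.
#'
#' @param positions marker positions on one linkage group, cM.
#' @param floor_cM minimum bandwidth returned, cM.
#' @return bandwidth h in cM.
#' @export
select_bandwidth <- function(positions, floor_cM = 1) {
  positions <- positions[!is.na(positions)]
  h <- NA_real_
  if (length(positions) >= 5) {
    h <- tryCatch(stats::bw.SJ(positions, method = "dpi"),
                  error = function(e) NA_real_)
  }
  if (is.na(h)) {
    warning("plug-in bandwidth unavailable; falling back to Silverman rule")
    h <- tryCatch(stats::bw.nrd0(positions), error = function(e) 0)
  }
  max(h, floor_cM)
}

#' Sliding-window marker counts along a linkage group
#'
#' Slides a window of width \code{h} (the kernel bandwidth) along the
#' linkage group in steps of \code{step} cM, anchored at position 0, and
#' counts markers in each half-open window \code{[x, x+h)}. The final
#' partial window is dropped so that all counts share the same window area
#' and the Poisson rate is comparable across windows.
#'
#' @param positions marker positions, cM.
#' @param lg_length linkage-group length, cM.
#' @param h window width (bandwidth), cM.
#' @param step slide increment, cM (default 1).
#' @return data.frame \code{(start, count)}.
#' @export
window_counts <- function(positions, lg_length, h, step = 1) {
  stopifnot(h > 0, step > 0)
  if (h > lg_length) {
    warning("bandwidth exceeds linkage group length; single full window")
    return(data.frame(start = 0,
                      count = sum(positions >= 0 & positions <= lg_length)))
  }
  starts <- seq(0, lg_length - h, by = step)
  counts <- vapply(starts, function(s)
    sum(positions >= s & positions < s + h), integer(1))
  data.frame(start = starts, count = counts)
}

#' Poisson thresholds for hotspot/coldspot calling
#'
#' Under a random (uniform) marker distribution, window counts follow a
#' Poisson law with rate lambda = mean markers per window. Coldspots of
#' recombination appear as windows with an excess of tightly packed
#' markers, hotspots as windows with a deficit. The coldspot threshold
#' \code{k_cold} is the smallest count k in the upper tail at which the
#' observed number of windows with count >= k exceeds the Poisson
#' expectation and a one-cell chi-square on that pooled tail is significant
#' at \code{alpha}; \code{k_hot} is the largest k in the lower tail at
#' which windows with count <= k are in significant excess. Thresholds are
#' computed on all windows of a map pooled (not per linkage group), where
#' expected counts are large enough for the chi-square to be trustworthy.
#'
#' A pooled tail only qualifies while its expected window count is at
#' least \code{min_expected} (Cochran's rule): the chi-square approximation
#' is unreliable for smaller expectations, and without this guard a single
#' extreme window in the far tail can masquerade as a threshold.
#'
#' @param counts integer window counts over the whole map.
#' @param alpha significance level (default 0.01).
#' @param min_windows minimum number of windows required.
#' @param min_expected minimum expected pooled-tail count for a candidate
#'   threshold (default 5).
#' @return list \code{(lambda, k_cold, k_hot, table)}; thresholds are
#'   \code{NA} when no count qualifies. \code{table} reports, per k, the
#'   observed and expected pooled-tail window counts and the chi-square
#'   p-value.
#' @export
poisson_thresholds <- function(counts, alpha = 0.01, min_windows = 50,
                               min_expected = 5) {
  nw <- length(counts)
  if (nw < min_windows)
    stop("too few windows (", nw, ") for threshold estimation")
  lambda <- mean(counts)
  kmax <- max(counts, stats::qpois(1 - 1e-9, lambda))
  tab <- list()
  one_cell <- function(obs, expd) {
    if (expd <= 0) return(1)
    stats::pchisq((obs - expd)^2 / expd, df = 1, lower.tail = FALSE)
  }
  # upper tail: candidate coldspot thresholds
  k_cold <- NA_integer_
  for (k in seq(floor(lambda) + 1, kmax + 1)) {
    obs <- sum(counts >= k)
    expd <- nw * stats::ppois(k - 1, lambda, lower.tail = FALSE)
    p <- one_cell(obs, expd)
    tab[[length(tab) + 1]] <- data.frame(tail = "upper", k = k, obs = obs,
                                         expected = expd, p_value = p)
    if (is.na(k_cold) && expd >= min_expected && obs > expd && p <= alpha)
      k_cold <- k
  }
  # lower tail: candidate hotspot thresholds
  k_hot <- NA_integer_
  if (lambda > 0) {
    for (k in seq(0, max(ceiling(lambda) - 1, 0))) {
      obs <- sum(counts <= k)
      expd <- nw * stats::ppois(k, lambda)
      p <- one_cell(obs, expd)
      tab[[length(tab) + 1]] <- data.frame(tail = "lower", k = k, obs = obs,
                                           expected = expd, p_value = p)
      if (expd >= min_expected && obs > expd && p <= alpha) k_hot <- k
    }
  }
  list(lambda = lambda, k_cold = k_cold, k_hot = k_hot,
       table = do.call(rbind, tab))
}

#' Recombination landscape of a genetic map
#'
#' Per linkage group: plug-in bandwidth, 1-cM sliding-window counts;
#' map-wide: Poisson thresholds and called hotspot/coldspot intervals.
#'
#' @param map a \code{genetic_map}.
#' @param step slide increment, cM.
#' @param alpha threshold significance level.
#' @param h optional fixed bandwidth overriding the per-LG plug-in choice.
#' @return object of class \code{landscape_profile}: list with
#'   \code{windows} (lg, start, count, h), \code{lambda}, \code{k_cold},
#'   \code{k_hot}, \code{intervals} (kind, lg, start, end, peak).
#' @export
landscape_profile <- function(map, step = 1, alpha = 0.01, h = NULL) {
  wins <- list()
  for (g in unique(map$lg)) {
    pos <- map$pos_cM[map$lg == g]
    pos <- pos - min(pos)
    hg <- if (is.null(h)) select_bandwidth(pos) else h
    wc <- window_counts(pos, max(pos), hg, step)
    wins[[g]] <- data.frame(lg = g, start = wc$start, count = wc$count,
                            h = hg, stringsAsFactors = FALSE)
  }
  windows <- do.call(rbind, wins)
  rownames(windows) <- NULL
  th <- poisson_thresholds(windows$count, alpha = alpha)
  intervals <- call_intervals(windows, th$k_cold, th$k_hot)
  structure(list(windows = windows, lambda = th$lambda,
                 k_cold = th$k_cold, k_hot = th$k_hot,
                 threshold_table = th$table, intervals = intervals,
                 step = step, alpha = alpha),
            class = "landscape_profile")
}

#' Call hotspot/coldspot intervals from thresholded windows
#'
#' Maximal runs of consecutive windows at or beyond a threshold are merged
#' into one interval per run, spanning from the first window start to the
#' last window start plus the bandwidth. Runs are never merged across a
#' window that fails the threshold.
#'
#' @param windows data.frame \code{(lg, start, count, h)} as produced by
#'   [landscape_profile()].
#' @param k_cold,k_hot thresholds ([poisson_thresholds()]); \code{NA}
#'   disables the corresponding kind.
#' @return data.frame \code{(kind, lg, start, end, peak)}.
#' @export
call_intervals <- function(windows, k_cold, k_hot) {
  out <- list()
  runs_of <- function(flag, sub, kind, peak_fun) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      i1 <- starts[j]; i2 <- ends[j]
      out[[length(out) + 1]] <<- data.frame(
        kind = kind, lg = sub$lg[1], start = sub$start[i1],
        end = sub$start[i2] + sub$h[1],
        peak = peak_fun(sub$count[i1:i2]), stringsAsFactors = FALSE)
    }
  }
  for (g in unique(windows$lg)) {
    sub <- windows[windows$lg == g, , drop = FALSE]
    if (!is.na(k_cold))
      runs_of(sub$count >= k_cold, sub, "coldspot", max)
    if (!is.na(k_hot))
      runs_of(sub$count <= k_hot, sub, "hotspot", min)
  }
  if (!length(out))
    return(data.frame(kind = character(0), lg = character(0),
                      start = numeric(0), end = numeric(0),
                      peak = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$kind, res$lg, res$start), , drop = FALSE]
}

#' Match hotspot/coldspot intervals across maps
#'
#' Aligns homologous linkage groups of 2-3 maps through shared anchor
#' markers (piecewise-linear projection between anchors, constant
#' extrapolation beyond the terminal ones) and matches intervals of the
#' same kind whose projected spans overlap. Matched intervals are merged
#' into clusters (connected components of the overlap relation); each
#' cluster is labelled by the number of maps it spans.
#'
#' @param features named list (one element per map) of interval tables
#'   ([call_intervals()] output).
#' @param maps named list of the corresponding \code{genetic_map}s, used
#'   as anchor sources (shared marker ids define the projections).
#' @param min_anchors linkage groups with fewer shared anchors are excluded
#'   from cross-map matching, with a warning.
#' @return list \code{(clusters, venn)}: \code{clusters} is a data.frame
#'   (cluster, map, kind, lg, start, end), \code{venn} a per-kind table of
#'   cluster counts by number of maps spanned.
#' @export
match_intervals <- function(features, maps, min_anchors = 2) {
  stopifnot(length(features) >= 2, identical(names(features), names(maps)))
  mnames <- names(features)
  feats <- do.call(rbind, lapply(mnames, function(mn) {
    f <- features[[mn]]
    if (!nrow(f)) return(NULL)
    cbind(map = mn, f, stringsAsFactors = FALSE)
  }))
  if (is.null(feats) || !nrow(feats))
    return(list(clusters = data.frame(), venn = data.frame()))
  n <- nrow(feats)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  for (a in seq_len(length(mnames) - 1)) for (b in seq(a + 1, length(mnames))) {
    ma <- mnames[a]; mb <- mnames[b]
    ia <- which(feats$map == ma); ib <- which(feats$map == mb)
    for (i in ia) {
      pr <- tryCatch(
        project_interval(feats$lg[i], c(feats$start[i], feats$end[i]),
                         maps[[ma]], maps[[mb]]),
        error = function(e) NULL)
      if (is.null(pr)) next
      n_anchor <- length(intersect(
        maps[[ma]]$marker_id[maps[[ma]]$lg == feats$lg[i]],
        maps[[mb]]$marker_id))
      if (n_anchor < min_anchors) {
        warning("linkage group ", feats$lg[i], " has fewer than ",
                min_anchors, " anchors between ", ma, " and ", mb,
                "; excluded from matching", call. = FALSE)
        next
      }
      lo <- min(pr$pos); hi <- max(pr$pos)
      for (j in ib) {
        if (feats$kind[j] != feats$kind[i]) next
        if (feats$lg[j] != pr$lg) next
        if (feats$start[j] < hi && feats$end[j] > lo) union_(i, j)
      }
    }
  }
  cluster <- vapply(seq_len(n), find, integer(1))
  cluster <- match(cluster, unique(cluster))
  clusters <- cbind(cluster = cluster, feats, stringsAsFactors = FALSE)
  venn <- do.call(rbind, lapply(split(clusters, clusters$kind), function(s) {
    span <- tapply(s$map, s$cluster, function(m) length(unique(m)))
    data.frame(kind = s$kind[1],
               n_clusters = length(span),
               specific = sum(span == 1),
               shared_two = sum(span == 2),
               shared_all = sum(span == length(mnames)),
               stringsAsFactors = FALSE)
  }))
  rownames(venn) <- NULL
  list(clusters = clusters, venn = venn)
}

#' Jaccard similarity of two maps' feature sets
#'
#' With \code{m} matched feature pairs between sets of sizes \code{nA} and
#' \code{nB}, the index is \code{m / (nA + nB - m)}; both sets empty gives
#' \code{NA} (undefined) with a message.
#'
#' @param featuresA,featuresB interval tables for the two maps.
#' @param mapA,mapB the corresponding \code{genetic_map}s (anchor sources).
#' @return numeric in \code{[0, 1]}, or \code{NA}.
#' @export
jaccard_features <- function(featuresA, featuresB, mapA, mapB) {
  nA <- nrow(featuresA); nB <- nrow(featuresB)
  if (nA + nB == 0) {
    message("both feature sets empty: Jaccard index undefined")
    return(NA_real_)
  }
  mt <- match_intervals(list(A = featuresA, B = featuresB),
                        list(A = mapA, B = mapB))
  span <- tapply(mt$clusters$map, mt$clusters$cluster,
                 function(m) length(unique(m)))
  m <- sum(span == 2)
  m / (nA + nB - m)
}

#' Mean features per chromosome
#'
#' @param counts per-map feature counts (one number per map).
#' @param n_chromosomes haploid chromosome number.
#' @return mean features per chromosome over all maps, one decimal.
#' @examples
#' summarize_features(c(71, 62, 69), 12)  # 5.6 hotspots per chromosome
#' @export
summarize_features <- function(counts, n_chromosomes) {
  if (n_chromosomes == 0) stop("n_chromosomes must be positive")
  round(sum(counts) / (length(counts) * n_chromosomes), 1)
}

#' @export
print.landscape_profile <- function(x, ...) {
  cat("landscape_profile:", nrow(x$windows), "windows, lambda =",
      round(x$lambda, 2), "\n")
  cat("  thresholds: coldspot k >=", x$k_cold, "; hotspot k <=", x$k_hot, "\n")
  if (nrow(x$intervals))
    print(table(x$intervals$kind))
  invisible(x)
}
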
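#' Chi-square goodness-of-fit test against a Mendelian ratio
#'
#' Pearson chi-square of observed genotype-class counts against an expected
#' segregation ratio (1:1 for testcross markers, 1:2:1 for codominant F2 or
#' intercross markers). No continuity correction and no multiple-testing
#' adjustment are applied: each marker is tested at the raw significance
#' level (\code{alpha}, default 0.01). With many markers a fraction
#' \code{alpha} of non-distorted markers is expected to be flagged; the
#' clustering step ([detect_sdr()]) and a validation cohort are what
#' separate real segregation distortion from these false positives.
#'
#' @param counts non-negative integer counts per genotype class.
#' @param ratio expected ratio, same length as \code{counts}.
#' @param alpha significance level for the \code{distorted} flag.
#' @param marker_id optional id carried into the result.
#' @return list \code{(marker_id, counts, ratio, chi2, df, p_value,
#'   distorted)}.
#' @examples
#' chi2_ratio_test(c(25, 50, 25), c(1, 2, 1))   # perfect fit
#' chi2_ratio_test(c(23, 46, 0),  c(1, 2, 1))   # missing homozygote class
#' @export
chi2_ratio_test <- function(counts, ratio = c(1, 2, 1), alpha = 0.01,
                            marker_id = NA_character_) {
  if (length(counts) != length(ratio))
    stop("ratio does not match the number of genotype classes")
  if (any(counts < 0)) stop("negative counts")
  n <- sum(counts)
  if (n == 0) stop("zero total count")
  expected <- ratio / sum(ratio) * n
  if (any(expected < 5))
    warning("expected count below 5; chi-square approximation is rough")
  chi2 <- sum((counts - expected)^2 / expected)
  df <- length(counts) - 1
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  list(marker_id = marker_id, counts = counts, ratio = ratio,
       chi2 = chi2, df = df, p_value = p, distorted = p <= alpha)
}

#' Segregation tests for every marker of a population
#'
#' @param gm a \code{genotype_matrix}.
#' @param alpha significance level.
#' @return data.frame with one row per informative marker: counts, chi2,
#'   df, p_value, distorted.
#' @export
seg_test_all <- function(gm, alpha = 0.01) {
  ids <- gm$markers$marker_id[gm$markers$seg_type != "uninformative"]
  rows <- lapply(ids, function(m) {
    gc <- geno_counts(gm, m)
    if (sum(gc$counts) == 0) return(NULL)
    r <- suppressWarnings(
      chi2_ratio_test(gc$counts, gc$ratio, alpha, marker_id = m))
    data.frame(marker_id = m, n = sum(gc$counts),
               counts = paste(gc$counts, collapse = ":"),
               ratio = paste(gc$ratio, collapse = ":"),
               chi2 = r$chi2, df = r$df, p_value = r$p_value,
               distorted = r$distorted, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect segregation distortion regions (SDRs)
#'
#' Scans each linkage group in map order for maximal runs of markers
#' flagged as distorted. A tested, non-distorted marker breaks a run; a
#' marker without a test result (for example one not assayed in this
#' population) is skipped, but only while the gap between consecutive
#' distorted members stays within \code{max_gap_cM}. Runs with at least
#' \code{min_cluster} members become SDRs; shorter runs are reported as
#' singletons, which at alpha = 0.01 are mostly the expected false
#' positives of the per-marker test.
#'
#' @param map a \code{genetic_map} (or data.frame with \code{lg, marker_id,
#'   pos_cM}).
#' @param seg data.frame from [seg_test_all()].
#' @param min_cluster minimum number of distorted members (default 3).
#' @param max_gap_cM maximum spacing between consecutive distorted members
#'   across untested markers (default 10).
#' @return list with \code{regions} (data.frame \code{lg, start_cM, end_cM,
#'   n_distorted, members, status, stage, origin}) and \code{singletons}
#'   (data.frame \code{lg, marker_id, pos_cM}).
#' @export
detect_sdr <- function(map, seg, min_cluster = 3, max_gap_cM = 10) {
  unmapped <- setdiff(seg$marker_id, map$marker_id)
  if (length(unmapped))
    stop("tested markers absent from the map: ",
         paste(utils::head(unmapped, 5), collapse = ", "))
  st <- stats::setNames(seg$distorted, seg$marker_id)
  regions <- list(); singles <- list()
  for (g in unique(map$lg)) {
    sub <- map[map$lg == g, , drop = FALSE]
    sub <- sub[order(sub$pos_cM), , drop = FALSE]
    run <- character(0); run_pos <- numeric(0)
    flush <- function() {
      if (!length(run)) return()
      if (length(run) >= min_cluster) {
        regions[[length(regions) + 1]] <<- data.frame(
          lg = g, start_cM = min(run_pos), end_cM = max(run_pos),
          n_distorted = length(run),
          members = paste(run, collapse = ","),
          status = "candidate", stage = "undetermined",
          origin = NA_character_, stringsAsFactors = FALSE)
      } else {
        for (k in seq_along(run))
          singles[[length(singles) + 1]] <<- data.frame(
            lg = g, marker_id = run[k], pos_cM = run_pos[k],
            stringsAsFactors = FALSE)
      }
      run <<- character(0); run_pos <<- numeric(0)
    }
    for (i in seq_len(nrow(sub))) {
      m <- sub$marker_id[i]; p <- sub$pos_cM[i]
      if (!m %in% names(st)) next           # untested: does not break a run
      if (isTRUE(st[[m]])) {
        if (length(run) && p - run_pos[length(run_pos)] > max_gap_cM)
          flush()
        run <- c(run, m); run_pos <- c(run_pos, p)
      } else {
        flush()                             # tested non-distorted breaks
      }
    }
    flush()
  }
  empty_r <- data.frame(lg = character(0), start_cM = numeric(0),
                        end_cM = numeric(0), n_distorted = integer(0),
                        members = character(0), status = character(0),
                        stage = character(0), origin = character(0),
                        stringsAsFactors = FALSE)
  empty_s <- data.frame(lg = character(0), marker_id = character(0),
                        pos_cM = numeric(0), stringsAsFactors = FALSE)
  list(regions = if (length(regions)) do.call(rbind, regions) else empty_r,
       singletons = if (length(singles)) do.call(rbind, singles) else empty_s)
}

#' Contrast inbred and outbred SDRs to nominate deleterious loci
#'
#' A cluster of distorted markers seen in the selfed F2 but absent from the
#' corresponding region of both outbred parental maps is the signature of a
#' deleterious (sub)lethal allele revealed by inbreeding. Each F2 SDR is
#' projected onto the two outbred parental maps through shared anchor
#' markers (piecewise-linear interpolation) and retained as a candidate
#' only when the projected interval contains no distorted marker on either
#' parental map.
#'
#' @param sdr_f2 SDR table from [detect_sdr()] on the F2 map
#'   (\code{$regions}).
#' @param map_f2,map_g2f,map_g2m genetic maps.
#' @param seg_g2f,seg_g2m per-marker test tables for the outbred parents.
#' @param margin_cM widen the projected interval by this margin on each
#'   side before looking for distorted outbred markers.
#' @return the candidate subset of \code{sdr_f2}, with extra columns for
#'   the projected intervals.
#' @export
contrast_pedigrees <- function(sdr_f2, map_f2, map_g2f, map_g2m,
                               seg_g2f, seg_g2m, margin_cM = 0) {
  if (!nrow(sdr_f2)) return(sdr_f2)
  keep <- logical(nrow(sdr_f2))
  for (i in seq_len(nrow(sdr_f2))) {
    clean <- TRUE
    for (side in list(list(map = map_g2f, seg = seg_g2f),
                      list(map = map_g2m, seg = seg_g2m))) {
      pr <- project_interval(sdr_f2$lg[i],
                             c(sdr_f2$start_cM[i], sdr_f2$end_cM[i]),
                             map_f2, side$map)
      dist_ids <- side$seg$marker_id[side$seg$distorted]
      hit <- side$map$marker_id %in% dist_ids &
        side$map$lg == pr$lg &
        side$map$pos_cM >= min(pr$pos) - margin_cM &
        side$map$pos_cM <= max(pr$pos) + margin_cM
      if (any(hit)) clean <- FALSE
    }
    keep[i] <- clean
  }
  out <- sdr_f2[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Project an interval from one map onto another using shared (anchor)
# markers on the same linkage group; piecewise linear between anchors,
# constant extrapolation beyond the terminal anchors.
project_interval <- function(lg, interval, from_map, to_map) {
  a_from <- from_map[from_map$lg == lg, , drop = FALSE]
  shared <- intersect(a_from$marker_id, to_map$marker_id)
  if (length(shared) < 1)
    stop("no anchor markers shared with the target map on ", lg,
         ": cannot project")
  x <- a_from$pos_cM[match(shared, a_from$marker_id)]
  y <- to_map$pos_cM[match(shared, to_map$marker_id)]
  lg_to <- to_map$lg[match(shared[1], to_map$marker_id)]
  if (length(shared) == 1) {
    pos <- y + (interval - x)      # rigid shift through the single anchor
  } else {
    o <- order(x)
    pos <- stats::approx(x[o], y[o], xout = interval, rule = 2,
                         ties = mean)$y
  }
  list(lg = lg_to, pos = pos)
}

#' Validate an SDR in an independent, larger cohort
#'
#' Discovery cohorts in linkage studies are often small, so apparent marker
#' clusters can be statistical artefacts. Member markers of a candidate SDR
#' are re-tested in a second cohort; the region is \code{"validated"} when
#' a majority of the re-tested members remain distorted at \code{alpha},
#' otherwise \code{"rejected"}.
#'
#' @param candidate one row of an SDR table ([detect_sdr()]).
#' @param second_cohort a \code{genotype_matrix} genotyped at one or more
#'   member markers.
#' @param alpha significance level.
#' @return the row with \code{status} set, plus \code{n_members_tested} and
#'   \code{n_members_distorted}.
#' @export
validate_sdr <- function(candidate, second_cohort, alpha = 0.01) {
  members <- strsplit(candidate$members, ",")[[1]]
  present <- intersect(members, second_cohort$markers$marker_id)
  if (!length(present))
    stop("no member marker genotyped in the validation cohort")
  dist <- vapply(present, function(m) {
    gc <- geno_counts(second_cohort, m)
    suppressWarnings(
      chi2_ratio_test(gc$counts, gc$ratio, alpha)$distorted)
  }, logical(1))
  candidate$status <- if (sum(dist) > length(dist) / 2) "validated"
                      else "rejected"
  candidate$n_members_tested <- length(present)
  candidate$n_members_distorted <- sum(dist)
  candidate
}

#' Classify the selection stage behind an SDR
#'
#' Distortion restricted to a single parental (gametic) map points to
#' prezygotic selection (gamete abortion or dysfunction in that parent);
#' distortion in zygotic ratios, or mirrored on both parental maps, points
#' to postzygotic selection (differential zygote/seedling viability).
#'
#' @param female,male,zygote logical evidence flags: is the region
#'   distorted on the female map, the male map, in zygotic (for example,
#'   selfed F2) ratios? Use \code{NA} when unassessed.
#' @return \code{"prezygotic"}, \code{"postzygotic"} or
#'   \code{"undetermined"}.
#' @export
classify_stage <- function(female = NA, male = NA, zygote = NA) {
  f <- isTRUE(female); m <- isTRUE(male); z <- isTRUE(zygote)
  if (z || (f && m)) return("postzygotic")
  if (xor(f, m)) return("prezygotic")
  "undetermined"
}

#' Grandparental origin of the deficient allele in an SDR
#'
#' For a selfed F2 whose F1 parent's haplotype phase is known (haplotype 1
#' from the first grandparent, haplotype 2 from the second), the genotype
#' codes at SDR member markers identify which grandparental homozygote
#' class is in deficit. Counts are pooled over member markers (tightly
#' linked markers are near-replicates of the same test) and the deficit is
#' reported only when the pooled chi-square against 1:2:1 is significant.
#'
#' @param gm an F2 \code{genotype_matrix} whose design carries
#'   \code{grandparents} labels.
#' @param markers SDR member marker ids.
#' @param alpha significance level.
#' @return list \code{(counts, deficit_class, origin, p_value)};
#'   \code{deficit_class}/\code{origin} are \code{NA} when not significant.
#' @export
transmission_origin <- function(gm, markers, alpha = 0.01) {
  if (gm$population_type != "F2")
    stop("transmission analysis requires a selfed F2 population")
  gp <- gm$design$grandparents
  if (is.null(gp)) stop("unphased grandparents: origin labels unavailable")
  markers <- intersect(markers, gm$markers$marker_id)
  if (!length(markers)) stop("no SDR member markers in the matrix")
  pooled <- c(A = 0, H = 0, B = 0)
  for (m in markers) {
    gc <- geno_counts(gm, m)
    pooled <- pooled + gc$counts
  }
  r <- suppressWarnings(chi2_ratio_test(pooled, c(1, 2, 1), alpha))
  if (!r$distorted)
    return(list(counts = pooled, deficit_class = NA_character_,
                origin = NA_character_, p_value = r$p_value))
  deficit <- if (pooled["A"] <= pooled["B"]) "A" else "B"
  origin <- if (deficit == "A") gp[1] else gp[2]
  list(counts = pooled, deficit_class = deficit, origin = origin,
       p_value = r$p_value)
}
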
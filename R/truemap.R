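#' Ground-truth genetic map for the meiosis simulator
#'
#' A \code{true_map} holds the simulated genome: linkage groups with their
#' lengths, marker positions, optional per-parent local recombination-rate
#' modifier tracks, and an optional embryo-viability locus whose genotype
#' classes have differential fitness. It is the ground truth against which
#' map estimation, segregation-distortion detection and hotspot/coldspot
#' calling are benchmarked.
#'
#' @param linkage_groups data.frame with columns \code{lg} (identifier) and
#'   \code{length_cM} (> 0).
#' @param markers data.frame with columns \code{marker_id}, \code{lg},
#'   \code{pos_cM} and optionally \code{contig_id}. Positions are 0-based
#'   from the linkage-group start and must lie in \code{[0, length_cM]}.
#' @param rate_modifiers optional named list (one element per parent label),
#'   each a data.frame \code{lg, start, end, multiplier} describing a
#'   piecewise-constant recombination-rate multiplier over half-open cM
#'   intervals \code{[start, end)}; 1.0 is the genome-wide baseline.
#'   Uncovered stretches are filled with 1.0 when \code{complete = TRUE}.
#' @param viability_locus optional list \code{(lg, pos_cM, fitness)} where
#'   \code{fitness} is a named numeric vector in \code{[0, 1]} over offspring
#'   genotype classes \code{"11"}, \code{"12"}, \code{"22"} (haplotype-origin
#'   coding; \code{"12"} covers both heterozygous configurations). At least
#'   one class must have fitness 1.
#' @param complete fill modifier-track gaps with multiplier 1.0 instead of
#'   raising a configuration error.
#' @return An object of class \code{true_map}.
#' @examples
#' tm <- true_map(
#'   data.frame(lg = "LG1", length_cM = 100),
#'   data.frame(marker_id = paste0("M", 1:11), lg = "LG1",
#'              pos_cM = seq(0, 100, by = 10))
#' )
#' tm
#' @export
true_map <- function(linkage_groups, markers, rate_modifiers = NULL,
                     viability_locus = NULL, complete = TRUE) {
  stopifnot(is.data.frame(linkage_groups),
            all(c("lg", "length_cM") %in% names(linkage_groups)),
            is.data.frame(markers),
            all(c("marker_id", "lg", "pos_cM") %in% names(markers)))
  linkage_groups$lg <- as.character(linkage_groups$lg)
  if (anyDuplicated(linkage_groups$lg))
    stop("duplicate linkage group ids")
  if (any(linkage_groups$length_cM <= 0))
    stop("linkage group lengths must be positive")
  markers$lg <- as.character(markers$lg)
  markers$marker_id <- as.character(markers$marker_id)
  if (anyDuplicated(markers$marker_id))
    stop("duplicate marker ids")
  if (is.null(markers$contig_id)) markers$contig_id <- markers$marker_id
  bad_lg <- setdiff(markers$lg, linkage_groups$lg)
  if (length(bad_lg))
    stop("markers reference unknown linkage groups: ",
         paste(bad_lg, collapse = ", "))
  len <- stats::setNames(linkage_groups$length_cM, linkage_groups$lg)
  if (any(markers$pos_cM < 0 | markers$pos_cM > len[markers$lg]))
    stop("marker positions must lie within [0, linkage group length]")
  markers <- markers[order(markers$lg, markers$pos_cM), , drop = FALSE]
  rownames(markers) <- NULL

  if (!is.null(rate_modifiers)) {
    if (is.data.frame(rate_modifiers))  # single shared track
      rate_modifiers <- list(shared = rate_modifiers)
    rate_modifiers <- lapply(rate_modifiers, function(tr)
      normalize_track(tr, linkage_groups, complete = complete))
  }

  if (!is.null(viability_locus)) {
    stopifnot(all(c("lg", "pos_cM", "fitness") %in% names(viability_locus)))
    viability_locus$lg <- as.character(viability_locus$lg)
    fit <- viability_locus$fitness
    if (!viability_locus$lg %in% linkage_groups$lg)
      stop("viability locus on unknown linkage group")
    if (is.null(names(fit)) || !all(c("11", "12", "22") %in% names(fit)))
      stop("fitness must be named over genotype classes '11', '12', '22'")
    if (any(fit < 0 | fit > 1)) stop("fitness values must lie in [0, 1]")
    if (!any(fit == 1)) stop("at least one genotype class must have fitness 1")
    if (all(fit == 0)) stop("all fitness values are 0: impossible design")
  }

  structure(list(linkage_groups = linkage_groups, markers = markers,
                 rate_modifiers = rate_modifiers,
                 viability_locus = viability_locus),
            class = "true_map")
}

# Tidy one modifier track: sort, fill gaps with 1.0 (or error), validate.
normalize_track <- function(track, linkage_groups, complete = TRUE) {
  stopifnot(is.data.frame(track),
            all(c("lg", "start", "end", "multiplier") %in% names(track)))
  track$lg <- as.character(track$lg)
  if (any(track$multiplier <= 0)) stop("rate multipliers must be > 0")
  if (any(track$end <= track$start)) stop("modifier intervals must have end > start")
  len <- stats::setNames(linkage_groups$length_cM, linkage_groups$lg)
  out <- list()
  for (g in unique(track$lg)) {
    if (!g %in% names(len)) stop("modifier track references unknown lg: ", g)
    tr <- track[track$lg == g, , drop = FALSE]
    tr <- tr[order(tr$start), , drop = FALSE]
    if (any(tr$start < 0) || any(tr$end > len[g]))
      stop("modifier interval outside linkage group ", g)
    if (any(tr$start[-1] < tr$end[-nrow(tr)]))
      stop("overlapping modifier intervals on ", g)
    # fill uncovered stretches with baseline 1.0
    edges <- sort(unique(c(0, tr$start, tr$end, len[[g]])))
    filled <- data.frame(lg = g, start = edges[-length(edges)],
                         end = edges[-1], multiplier = 1.0)
    for (i in seq_len(nrow(tr))) {
      hit <- filled$start >= tr$start[i] & filled$end <= tr$end[i]
      filled$multiplier[hit] <- tr$multiplier[i]
    }
    covered <- sum(tr$end - tr$start)
    if (!complete && covered < len[[g]] - 1e-9)
      stop("modifier track does not cover linkage group ", g,
           ": configuration error")
    out[[g]] <- filled
  }
  do.call(rbind, out)
}

# Piecewise-constant track for one lg -> cumulative warped distance helpers.
# W(x) = integral_0^x m(u) du on [0, L]; inverse maps warped -> physical cM.
warp_fun <- function(track_lg) {
  s <- track_lg$start; e <- track_lg$end; m <- track_lg$multiplier
  cumw <- c(0, cumsum((e - s) * m))
  list(
    forward = function(x) {
      i <- findInterval(x, s, rightmost.closed = TRUE)
      i[i < 1] <- 1
      cumw[i] + (x - s[i]) * m[i]
    },
    backward = function(w) {
      i <- findInterval(w, cumw, rightmost.closed = TRUE)
      i[i > length(m)] <- length(m)
      i[i < 1] <- 1
      s[i] + (w - cumw[i]) / m[i]
    },
    total = cumw[length(cumw)]
  )
}

# Resolve the modifier track for one parent and lg (baseline if absent).
parent_track <- function(map, parent, lg) {
  L <- map$linkage_groups$length_cM[map$linkage_groups$lg == lg]
  baseline <- data.frame(lg = lg, start = 0, end = L, multiplier = 1.0)
  rm <- map$rate_modifiers
  if (is.null(rm)) return(baseline)
  tr <- if (!is.null(rm[[parent]])) rm[[parent]] else rm[["shared"]]
  if (is.null(tr)) return(baseline)
  tr <- tr[tr$lg == lg, , drop = FALSE]
  if (!nrow(tr)) return(baseline)
  tr
}

#' @export
print.true_map <- function(x, ...) {
  cat("true_map:", nrow(x$linkage_groups), "linkage group(s),",
      nrow(x$markers), "markers\n")
  cat("  total length:", sum(x$linkage_groups$length_cM), "cM\n")
  if (!is.null(x$rate_modifiers))
    cat("  rate-modifier tracks for:",
        paste(names(x$rate_modifiers), collapse = ", "), "\n")
  if (!is.null(x$viability_locus))
    cat("  viability locus on", x$viability_locus$lg, "at",
        x$viability_locus$pos_cM, "cM; fitness:",
        paste(names(x$viability_locus$fitness),
              x$viability_locus$fitness, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Regular synthetic true map
#'
#' Convenience constructor for simulation studies: \code{n_lg} linkage groups
#' of equal length with markers on a regular grid. Defaults mirror a conifer
#' mapping design: 12 chromosomes of 120 cM.
#'
#' @param n_lg number of linkage groups.
#' @param length_cM length of each linkage group, cM.
#' @param spacing_cM distance between adjacent markers, cM.
#' @param rate_modifiers,viability_locus passed to [true_map()].
#' @return A \code{true_map}.
#' @export
grid_true_map <- function(n_lg = 12, length_cM = 120, spacing_cM = 2,
                          rate_modifiers = NULL, viability_locus = NULL) {
  lgs <- data.frame(lg = sprintf("LG%02d", seq_len(n_lg)),
                    length_cM = length_cM)
  mk <- do.call(rbind, lapply(lgs$lg, function(g) {
    pos <- seq(0, length_cM, by = spacing_cM)
    data.frame(marker_id = sprintf("%s_M%03d", g, seq_along(pos)),
               lg = g, pos_cM = pos,
               contig_id = sprintf("%s_C%03d", g, seq_along(pos)))
  }))
  true_map(lgs, mk, rate_modifiers = rate_modifiers,
           viability_locus = viability_locus)
}
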
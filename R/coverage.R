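#' Observed genome length
#'
#' Sum of linkage-group map lengths, plus an optional fixed adjustment for
#' known gaps (for example, 50 cM when a chromosome is split into two
#' subgroups by a coverage gap).
#'
#' @param lg_lengths numeric vector of per-LG map lengths (cM), or a
#'   \code{genetic_map} from which spans are taken.
#' @param gap_adjust_cM non-negative adjustment added to the sum.
#' @return G0 in cM.
#' @export
observed_length <- function(lg_lengths, gap_adjust_cM = 0) {
  if (inherits(lg_lengths, "genetic_map") || is.data.frame(lg_lengths))
    lg_lengths <- lg_spans(lg_lengths)
  if (!length(lg_lengths)) stop("empty map")
  if (gap_adjust_cM < 0) stop("gap adjustment must be non-negative")
  sum(lg_lengths) + gap_adjust_cM
}

#' Per-linkage-group spans of a genetic map
#' @param map a \code{genetic_map}.
#' @param role optionally restrict to \code{"framework"} markers.
#' @return named numeric vector of spans (max - min position) in cM.
#' @export
lg_spans <- function(map, role = NULL) {
  if (!is.null(role)) map <- map[map$role %in% role, , drop = FALSE]
  vapply(split(map$pos_cM, map$lg), function(p) max(p) - min(p), numeric(1))
}

#' Expected genome length (Chakravarti method 4)
#'
#' Inflates each linkage group by \eqn{(m+1)/(m-1)}, where \eqn{m} is its
#' number of framework markers, under the assumption of uniformly
#' distributed marker locations; the terminal chromosome segments beyond
#' the outermost markers are the part a map cannot see.
#' \deqn{G_e = \sum_i L_i (m_i + 1)/(m_i - 1)}
#'
#' @param lg_lengths per-LG observed lengths (cM).
#' @param m per-LG framework marker counts (each >= 2).
#' @return Ge in cM.
#' @examples
#' expected_length_chakravarti(120, 25)  # 120 * 26/24 = 130
#' @export
expected_length_chakravarti <- function(lg_lengths, m) {
  stopifnot(length(lg_lengths) == length(m))
  if (any(m < 2)) stop("each linkage group needs at least 2 markers")
  sum(lg_lengths * (m + 1) / (m - 1))
}

#' Observed map coverage
#'
#' @param G0 observed genome length (cM).
#' @param Ge expected genome length (cM).
#' @param digits rounding for the reported percentage (default whole
#'   percent, as conventionally printed).
#' @return Co as a percentage.
#' @examples
#' observed_coverage(1708, 1745)  # 98
#' @export
observed_coverage <- function(G0, Ge, digits = 0) {
  if (Ge <= 0) stop("Ge must be positive")
  round(100 * G0 / Ge, digits)
}

#' Expected map coverage (Bishop estimator)
#'
#' Probability that a random genome location lies within \code{X} cM of a
#' mapped marker, for \code{N} markers distributed over \code{R}
#' chromosomes of total expected length \code{Ge}:
#' \deqn{C_e = 1 - \left[\frac{2R}{N+1}\left(\left(1-\frac{X}{2G_e}\right)^{N+1}
#'  - \left(1-\frac{X}{G_e}\right)^{N+1}\right)
#'  + \left(1-\frac{RX}{G_e}\right)\left(1-\frac{X}{G_e}\right)^{N}\right]}
#' clamped to \code{[0, 1]}. Sanity limits: \code{X = 0} gives 0 (a zero
#' window covers nothing) and \code{N} large gives 1 (saturation).
#'
#' @param R haploid chromosome number.
#' @param N number of framework loci.
#' @param X window length, cM (the maximum accepted gap between adjacent
#'   markers at the chosen LOD support).
#' @param Ge expected genome length, cM.
#' @return Ce in \code{[0, 1]}.
#' @export
expected_coverage_bishop <- function(R, N, X, Ge) {
  stopifnot(R >= 1, N >= 1, X >= 0)
  if (X > Ge) stop("window length X exceeds the genome length")
  ce <- 1 - ((2 * R / (N + 1)) *
               ((1 - X / (2 * Ge))^(N + 1) - (1 - X / Ge)^(N + 1)) +
             (1 - R * X / Ge) * (1 - X / Ge)^N)
  min(max(ce, 0), 1)
}

#' Marker density of a map
#'
#' @param G0 observed genome length (cM).
#' @param n_mapped number of mapped markers (framework + accessory).
#' @return cM per locus, one decimal.
#' @examples
#' marker_density(1708, 1121)  # 1.5
#' @export
marker_density <- function(G0, n_mapped) {
  if (n_mapped < 1) stop("no mapped markers")
  round(G0 / n_mapped, 1)
}

#' Genome length and coverage summary for a map
#'
#' @param map a \code{genetic_map}.
#' @param R haploid chromosome number (default: number of linkage groups).
#' @param X Bishop window length, cM (a required analysis choice: the
#'   maximum accepted adjacent-marker gap at the chosen LOD support).
#' @param gap_adjust_cM added to G0 for known inter-subgroup gaps.
#' @return list of class \code{coverage_stats} with \code{G0, Ge, Co, Ce,
#'   R, N, X, density_cM_per_locus} and the per-LG table.
#' @export
coverage_stats <- function(map, R = NULL, X = 30, gap_adjust_cM = 0) {
  spans_all <- lg_spans(map)
  spans_fw <- lg_spans(map, role = "framework")
  m <- vapply(split(map$role, map$lg),
              function(r) sum(r == "framework"), numeric(1))
  if (is.null(R)) R <- length(spans_all)
  G0 <- observed_length(spans_all, gap_adjust_cM)
  Ge <- expected_length_chakravarti(spans_fw[names(m)], m)
  N <- sum(m)
  structure(list(
    G0 = G0, Ge = Ge, Co = observed_coverage(G0, Ge),
    Ce = expected_coverage_bishop(R, N, X, Ge),
    R = R, N = N, X = X,
    density_cM_per_locus = marker_density(G0, nrow(map)),
    per_lg = data.frame(lg = names(m), length_cM = spans_all[names(m)],
                        m_framework = m, row.names = NULL)),
    class = "coverage_stats")
}

#' @export
print.coverage_stats <- function(x, ...) {
  cat(sprintf(paste0("coverage_stats: G0 = %.0f cM, Ge = %.0f cM, ",
                     "Co = %.0f%%, Ce = %.3f\n"), x$G0, x$Ge, x$Co, x$Ce))
  cat(sprintf("  R = %d chromosomes, N = %d framework loci, X = %g cM, %s cM/locus\n",
              x$R, x$N, x$X, format(x$density_cM_per_locus)))
  invisible(x)
}
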
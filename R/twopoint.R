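#' Kosambi map function
#'
#' Converts a recombination fraction to a Kosambi map distance and back.
#' The Kosambi function, \eqn{d = \frac{1}{4}\ln\frac{1+2\theta}{1-2\theta}}
#' (in Morgans), allows for moderate crossover interference and is the
#' standard choice in conifer linkage mapping.
#'
#' @param theta recombination fraction in \code{[0, 0.5)}.
#' @param cM map distance in centimorgans.
#' @return \code{kosambi_cm}: distance in cM; \code{kosambi_rf}: the
#'   recombination fraction \eqn{\theta = \frac{1}{2}\tanh(2d)}.
#' @examples
#' kosambi_cm(0.25)        # 25 * log(3) ~ 27.47 cM
#' kosambi_rf(10)          # ~ 0.0987
#' @export
kosambi_cm <- function(theta) {
  if (any(theta < 0 | theta >= 0.5))
    stop("theta must lie in [0, 0.5)")
  25 * log((1 + 2 * theta) / (1 - 2 * theta))
}

#' @rdname kosambi_cm
#' @export
kosambi_rf <- function(cM) {
  if (any(cM < 0)) stop("distance must be non-negative")
  0.5 * tanh(cM / 50)
}

# LOD of linkage for a testcross pair: likelihood ratio at theta-hat vs 0.5,
# with the 0*log(0) = 0 convention at the boundaries.
testcross_lod <- function(R, n) {
  theta <- R / n
  xlx <- function(k, p) if (k == 0) 0 else k * log10(p)
  n * log10(2) + xlx(R, theta) + xlx(n - R, 1 - theta)
}

#' Two-point linkage for testcross (1:1) markers
#'
#' Estimates the recombination fraction between two markers segregating 1:1
#' for the same parent of a CP family. Calls are reduced to the transmitted
#' parental allele; with unknown phase the orientation giving
#' \eqn{\hat\theta \le 0.5} is kept and reported as coupling/repulsion.
#' \eqn{\hat\theta} = recombinants / n over pairwise-complete individuals;
#' LOD \eqn{= n\log_{10}2 + R\log_{10}\hat\theta + (n-R)\log_{10}(1-\hat\theta)}.
#'
#' @param calls_a,calls_b call vectors (codes \code{ll/lm} or \code{nn/np},
#'   missing \code{"--"}), same parent, same individuals.
#' @return list \code{(rf, lod, n_informative, phase)}.
#' @export
rf_testcross <- function(calls_a, calls_b) {
  stopifnot(length(calls_a) == length(calls_b))
  to01 <- function(x) ifelse(x %in% c("lm", "np"), 1L,
                             ifelse(x %in% c("ll", "nn"), 0L, NA_integer_))
  a <- to01(calls_a); b <- to01(calls_b)
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n == 0) stop("no pairwise-complete individuals")
  mism <- sum(a[ok] != b[ok])
  phase <- if (mism <= n - mism) "coupling" else "repulsion"
  R <- min(mism, n - mism)
  theta <- min(R / n, 0.5)
  list(rf = theta, lod = testcross_lod(R, n), n_informative = n,
       phase = phase)
}

# F2 intercross joint class probabilities for one phase.
# r = recombination fraction; coupling F1 = AB/ab. Rows/cols in order
# (A,H,B) x (A,H,B) for markers 1 and 2. Repulsion swaps r and 1-r.
f2_cell_probs <- function(r, phase = "coupling") {
  if (phase == "repulsion") r <- 1 - r
  s <- 1 - r
  p <- matrix(c(s^2,       2 * r * s,     r^2,
                2 * r * s, 2 * (s^2 + r^2), 2 * r * s,
                r^2,       2 * r * s,     s^2) / 4,
              3, 3, byrow = TRUE)
  p
}

# Expected recombinant gametes (out of 2) per cell, used by the EM step.
f2_exp_rec <- function(r, phase = "coupling") {
  if (phase == "repulsion") r <- 1 - r
  s <- 1 - r
  dh <- if (s^2 + r^2 > 0) 2 * r^2 / (s^2 + r^2) else 1
  e <- matrix(c(0, 1, 2,
                1, dh, 1,
                2, 1, 0), 3, 3, byrow = TRUE)
  if (phase == "repulsion") e <- 2 - e
  e
}

f2_loglik <- function(r, tab, phase) {
  p <- f2_cell_probs(r, phase)
  sum(tab[p > 0] * log(p[p > 0]))
}

#' Two-point linkage for codominant F2 (1:2:1) markers
#'
#' Maximum-likelihood recombination fraction between two codominant markers
#' of a selfed F2, via EM over the 3 x 3 genotype table (the double
#' heterozygote is the ambiguous class). Both linkage phases are fitted and
#' the better-supported one kept; LOD is the log10 likelihood ratio against
#' \eqn{\theta = 0.5}.
#'
#' @param calls_a,calls_b call vectors with codes \code{A/H/B} (or
#'   \code{hh/hk/kk}), missing \code{U}/\code{--}.
#' @param tol EM convergence tolerance on \eqn{\theta}.
#' @return list \code{(rf, lod, n_informative, phase)}.
#' @export
rf_f2 <- function(calls_a, calls_b, tol = 1e-8) {
  stopifnot(length(calls_a) == length(calls_b))
  lv <- c("A", "H", "B")
  norm <- function(x) {
    x[x == "hh"] <- "A"; x[x == "hk"] <- "H"; x[x == "kk"] <- "B"
    factor(x, levels = lv)
  }
  a <- as.integer(norm(calls_a)); b <- as.integer(norm(calls_b))
  ok <- !is.na(a) & !is.na(b)
  n <- sum(ok)
  if (n == 0) stop("no pairwise-complete individuals")
  tab <- matrix(tabulate((a[ok] - 1L) * 3L + b[ok], 9L), 3, 3, byrow = TRUE)
  if (sum(rowSums(tab) > 0) < 2 || sum(colSums(tab) > 0) < 2)
    stop("degenerate table: a marker is monomorphic in the complete cases")
  fit_phase <- function(phase) {
    r <- 0.25
    for (it in 1:1000) {
      rec <- sum(tab * f2_exp_rec(r, phase)) / (2 * n)
      if (abs(rec - r) < tol) { r <- rec; break }
      r <- rec
    }
    r <- min(max(r, 0), 0.5)
    list(r = r, ll = f2_loglik(r, tab, phase))
  }
  fc <- fit_phase("coupling"); fr <- fit_phase("repulsion")
  best <- if (fc$ll >= fr$ll) c(fc, phase = "coupling")
          else c(fr, phase = "repulsion")
  lod <- (best$ll - f2_loglik(0.5, tab, best$phase)) / log(10)
  list(rf = best$r, lod = max(lod, 0), n_informative = n,
       phase = best$phase)
}

#' All pairwise two-point linkages
#'
#' Computes recombination fraction and LOD for every marker pair that the
#' population design makes estimable: for a CP family, testcross pairs
#' informative for the same parent (\code{parent = "mother"} selects
#' \code{lmxll} markers, \code{"father"} \code{nnxnp}); for an F2, all
#' codominant pairs. Missing data are handled by pairwise-complete deletion.
#'
#' @param gm a \code{genotype_matrix}.
#' @param parent for CP populations, which parent's testcross markers to use.
#' @param markers optional subset of marker ids.
#' @return data.frame \code{(marker_a, marker_b, rf, lod, n_informative,
#'   phase)}.
#' @export
pairwise_linkage <- function(gm, parent = c("mother", "father"),
                             markers = NULL) {
  if (gm$population_type == "CP") {
    parent <- match.arg(parent)
    want <- if (parent == "mother") "lmxll" else "nnxnp"
    ids <- gm$markers$marker_id[gm$markers$seg_type == want]
    est <- rf_testcross
  } else {
    ids <- gm$markers$marker_id[gm$markers$seg_type == "f2"]
    est <- rf_f2
  }
  if (!is.null(markers)) ids <- intersect(ids, markers)
  if (length(ids) < 2) stop("fewer than two informative markers")
  pairs <- utils::combn(ids, 2)
  np <- ncol(pairs)
  rf <- lod <- numeric(np); ni <- integer(np); ph <- character(np)
  for (k in seq_len(np)) {
    z <- est(gm$calls[pairs[1, k], ], gm$calls[pairs[2, k], ])
    rf[k] <- z$rf; lod[k] <- z$lod
    ni[k] <- z$n_informative; ph[k] <- z$phase
  }
  data.frame(marker_a = pairs[1, ], marker_b = pairs[2, ], rf = rf,
             lod = lod, n_informative = ni, phase = ph,
             stringsAsFactors = FALSE)
}

#' Group markers by two-point linkage
#'
#' Transitive closure of marker pairs with LOD at or above the threshold:
#' two markers fall in the same linkage group when connected by a chain of
#' significant linkages. With a well-covered genome the number of groups
#' recovers the haploid chromosome number.
#'
#' @param linkages data.frame from [pairwise_linkage()].
#' @param lod_min LOD threshold (default 3).
#' @return list of character vectors of marker ids, largest first.
#' @export
group_markers <- function(linkages, lod_min = 3) {
  all_ids <- unique(c(linkages$marker_a, linkages$marker_b))
  keep <- linkages$lod >= lod_min
  g <- igraph::graph_from_data_frame(
    linkages[keep, c("marker_a", "marker_b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = all_ids))
  cmp <- igraph::components(g)
  groups <- split(names(cmp$membership), cmp$membership)
  groups <- groups[order(-vapply(groups, length, integer(1)))]
  unname(lapply(groups, as.character))
}

# Sum of adjacent rf along a candidate order (Inf for missing pairs).
order_cost <- function(ord, rfm) {
  sum(rfm[cbind(ord[-length(ord)], ord[-1])])
}

#' Order markers within a linkage group
#'
#' A transparent seriation heuristic: greedy chain extension from the
#' tightest-linked pair (always appending, at whichever end, the unplaced
#' marker with the smallest recombination fraction to an end marker),
#' refined by 2-opt segment reversals until no reversal reduces the sum of
#' adjacent recombination fractions. Positions are cumulative Kosambi
#' distances of adjacent pairs, starting at 0. Output orientation is fixed
#' by making the first marker id lexicographically smaller than the last,
#' so the result is invariant to input order (up to whole-group reversal,
#' which is unidentifiable from linkage data).
#'
#' @param group character vector of marker ids (one linkage group).
#' @param linkages data.frame from [pairwise_linkage()].
#' @return data.frame \code{(marker_id, pos_cM)} in map order.
#' @export
order_markers <- function(group, linkages) {
  if (length(group) == 1)
    return(data.frame(marker_id = group, pos_cM = 0))
  rfm <- matrix(Inf, length(group), length(group),
                dimnames = list(group, group))
  sel <- linkages$marker_a %in% group & linkages$marker_b %in% group
  lk <- linkages[sel, , drop = FALSE]
  rfm[cbind(lk$marker_a, lk$marker_b)] <- lk$rf
  rfm[cbind(lk$marker_b, lk$marker_a)] <- lk$rf
  diag(rfm) <- 0
  if (any(!is.finite(rfm)))
    stop("group is not fully connected by pairwise estimates")

  # greedy chain from the tightest pair
  start <- which(rfm == min(rfm + diag(Inf, nrow(rfm))), arr.ind = TRUE)[1, ]
  chain <- group[start]
  left <- setdiff(group, chain)
  while (length(left)) {
    dl <- rfm[chain[1], left]
    dr <- rfm[chain[length(chain)], left]
    if (min(dl) <= min(dr)) {
      chain <- c(left[which.min(dl)], chain)
      left <- setdiff(left, chain[1])
    } else {
      chain <- c(chain, left[which.min(dr)])
      left <- setdiff(left, chain[length(chain)])
    }
  }

  # 2-opt refinement on the open path
  n <- length(chain)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    cost <- order_cost(chain, rfm)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        cand <- chain
        cand[i:j] <- rev(cand[i:j])
        if (order_cost(cand, rfm) < cost - 1e-12) {
          chain <- cand
          cost <- order_cost(chain, rfm)
          improved <- TRUE
        }
      }
    }
  }
  if (chain[1] > chain[n]) chain <- rev(chain)
  adj <- rfm[cbind(chain[-n], chain[-1])]
  pos <- c(0, cumsum(kosambi_cm(pmin(adj, 0.4999))))
  data.frame(marker_id = chain, pos_cM = pos)
}

#' Attach an accessory marker to a framework map
#'
#' Places a marker (typically one with a less informative segregation type)
#' at its most probable location: the framework marker with the maximal
#' two-point LOD, recording the Kosambi distance and the supporting LOD.
#' LOD ties are broken toward the smaller distance (and logged).
#'
#' @param framework data.frame \code{(marker_id, pos_cM)} of the framework
#'   map for one linkage group.
#' @param marker accessory marker id.
#' @param linkages data.frame of two-point estimates including pairs
#'   between \code{marker} and framework markers.
#' @param lod_min minimum LOD to accept a placement.
#' @return data.frame \code{(marker_id, nearest_framework, attach_dist_cM,
#'   attach_lod)}, or NULL (with a message) when unlinked.
#' @export
place_accessory <- function(framework, marker, linkages, lod_min = 3) {
  sel <- (linkages$marker_a == marker & linkages$marker_b %in% framework$marker_id) |
         (linkages$marker_b == marker & linkages$marker_a %in% framework$marker_id)
  lk <- linkages[sel, , drop = FALSE]
  lk <- lk[lk$lod >= lod_min, , drop = FALSE]
  if (!nrow(lk)) {
    message("accessory marker ", marker, " unplaced: no linkage at LOD >= ",
            lod_min)
    return(NULL)
  }
  other <- ifelse(lk$marker_a == marker, lk$marker_b, lk$marker_a)
  best <- which(lk$lod == max(lk$lod))
  if (length(best) > 1) {
    message("LOD tie for ", marker, "; choosing smaller distance")
    best <- best[which.min(lk$rf[best])]
  }
  data.frame(marker_id = marker, nearest_framework = other[best],
             attach_dist_cM = kosambi_cm(min(lk$rf[best], 0.4999)),
             attach_lod = lk$lod[best], stringsAsFactors = FALSE)
}

#' Assemble a genetic map from genotype data
#'
#' Full two-point mapping for one dataset: groups framework markers at
#' \code{lod_min}, orders each group, then attaches accessory markers to
#' their best-supported framework location. For a CP population the
#' framework is the chosen parent's testcross (1:1) markers and the
#' intercross (1:2:1) markers are accessory; for an F2, all markers are
#' codominant and markers listed in \code{accessory} (if any) are attached
#' rather than ordered. One marker per contig is retained for the framework
#' (the first, or the one with most complete calls).
#'
#' @param gm a \code{genotype_matrix}.
#' @param parent CP parent ("mother"/"father").
#' @param lod_min grouping/placement LOD threshold.
#' @param one_per_contig drop all but one marker per contig before mapping
#'   (\code{"first"}, \code{"most_complete"}, or \code{"none"}).
#' @param min_group_size groups smaller than this are left unmapped.
#' @return A \code{genetic_map} data.frame: \code{lg, marker_id, pos_cM,
#'   role, nearest_framework, attach_dist_cM, attach_lod}.
#' @export
build_map <- function(gm, parent = c("mother", "father"), lod_min = 3,
                      one_per_contig = c("most_complete", "first", "none"),
                      min_group_size = 2) {
  one_per_contig <- match.arg(one_per_contig)
  mk <- gm$markers
  if (gm$population_type == "CP") {
    parent <- match.arg(parent)
    fw_type <- if (parent == "mother") "lmxll" else "nnxnp"
    acc_type <- "hkxhk"
  } else {
    parent <- "parent"
    fw_type <- "f2"
    acc_type <- NULL
  }
  fw_ids <- mk$marker_id[mk$seg_type == fw_type]
  if (one_per_contig != "none") {
    sub <- mk[mk$marker_id %in% fw_ids, , drop = FALSE]
    if (one_per_contig == "most_complete") {
      miss <- missing_code(gm$population_type)
      sub$n_called <- rowSums(gm$calls[sub$marker_id, , drop = FALSE] != miss)
      sub <- sub[order(sub$contig_id, -sub$n_called), , drop = FALSE]
    }
    fw_ids <- sub$marker_id[!duplicated(sub$contig_id)]
  }
  lk <- pairwise_linkage(gm, parent = parent, markers = fw_ids)
  groups <- group_markers(lk, lod_min = lod_min)
  groups <- groups[vapply(groups, length, integer(1)) >= min_group_size]
  maps <- lapply(seq_along(groups), function(i) {
    om <- order_markers(groups[[i]], lk)
    data.frame(lg = sprintf("LG%02d", i), marker_id = om$marker_id,
               pos_cM = om$pos_cM, role = "framework",
               nearest_framework = NA_character_,
               attach_dist_cM = NA_real_, attach_lod = NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, maps)

  if (!is.null(acc_type)) {
    acc_ids <- mk$marker_id[mk$seg_type == acc_type]
    for (m in acc_ids) {
      est <- lapply(out$marker_id, function(f) {
        z <- try(mixed_pair_rf(gm, m, f, parent), silent = TRUE)
        if (inherits(z, "try-error")) NULL else
          data.frame(marker_a = m, marker_b = f, rf = z$rf, lod = z$lod,
                     n_informative = z$n_informative, phase = z$phase,
                     stringsAsFactors = FALSE)
      })
      est <- do.call(rbind, est)
      if (is.null(est)) next
      pl <- place_accessory(out[, c("marker_id", "pos_cM")], m, est,
                            lod_min = lod_min)
      if (is.null(pl)) next
      fw_row <- out[out$marker_id == pl$nearest_framework, ]
      out <- rbind(out, data.frame(
        lg = fw_row$lg, marker_id = m,
        pos_cM = fw_row$pos_cM + pl$attach_dist_cM, role = "accessory",
        nearest_framework = pl$nearest_framework,
        attach_dist_cM = pl$attach_dist_cM, attach_lod = pl$attach_lod,
        stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$lg, out$pos_cM), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("genetic_map", "data.frame")
  out
}

# rf between an intercross (hkxhk) marker and a testcross marker of the
# given parent: the testcross call identifies that parent's transmitted
# allele; the intercross genotype identifies the transmitted alleles up to
# the double-heterozygote ambiguity. Treated as a one-parent-informative
# pair: testcross gamete vs intercross marker's gamete from the same
# parent, estimated by EM over the 2 x 3 table.
mixed_pair_rf <- function(gm, acc, fw, parent) {
  at <- gm$markers$seg_type[match(acc, gm$markers$marker_id)]
  ft <- gm$markers$seg_type[match(fw, gm$markers$marker_id)]
  if (at != "hkxhk" || !ft %in% c("lmxll", "nnxnp"))
    stop("unsupported pair types")
  a <- gm$calls[fw, ]   # testcross
  b <- gm$calls[acc, ]  # intercross
  t01 <- factor(ifelse(a %in% c("lm", "np"), 1L,
                       ifelse(a %in% c("ll", "nn"), 0L, NA_integer_)),
                levels = 0:1)
  bf <- factor(b, levels = c("hh", "hk", "kk"))
  ok <- !is.na(t01) & !is.na(bf)
  n <- sum(ok)
  if (n == 0) stop("no informative individuals")
  tab <- table(t01[ok], bf[ok])  # 2 x 3
  # The shared parent's gamete carries the intercross allele k with
  # probability 1-r or r depending on the transmitted testcross allele and
  # the (unknown) phase; the other parent's gamete is independent 1/2-1/2.
  ll <- function(r, phaseA) {
    q1 <- if (phaseA) 1 - r else r  # P(k from shared parent | testcross = 1)
    q0 <- 1 - q1
    p <- rbind(c((1 - q0) / 2, 1 / 2, q0 / 2),  # testcross call 0 row
               c((1 - q1) / 2, 1 / 2, q1 / 2))  # testcross call 1 row
    sum(tab * log(p))
  }
  fit <- function(phaseA) {
    o <- stats::optimize(function(r) -ll(r, phaseA), c(1e-6, 0.5))
    list(r = o$minimum, ll = -o$objective)
  }
  fa <- fit(TRUE); fb <- fit(FALSE)
  phaseA <- fa$ll >= fb$ll
  best <- if (phaseA) fa else fb
  lod <- (best$ll - ll(0.5, TRUE)) / log(10)
  list(rf = min(best$r, 0.5), lod = max(lod, 0), n_informative = n,
       phase = if (phaseA) "coupling" else "repulsion")
}

#' Same-contig genotyping consistency check
#'
#' Markers assayed from the same contig are physically so close that the
#' probability of a crossover between them is effectively zero; any
#' within-contig call disagreement is therefore a genotyping error. For
#' every same-contig marker pair and every individual with both calls
#' present, one comparison is counted; an event is counted when the calls
#' disagree after allele re-orientation (each pair is scored under both
#' allele orientations and the smaller disagreement count kept, so an
#' arbitrary allele labelling cannot inflate the rate).
#'
#' @param gm a \code{genotype_matrix}.
#' @param contigs optional named vector marker_id -> contig_id overriding
#'   the matrix metadata.
#' @return list \code{(n_comparisons, n_events, error_rate_pct)}.
#' @export
contig_consistency <- function(gm, contigs = NULL) {
  mk <- gm$markers
  cid <- if (is.null(contigs)) stats::setNames(mk$contig_id, mk$marker_id)
         else contigs[mk$marker_id]
  tab <- split(mk$marker_id, cid[mk$marker_id])
  tab <- tab[vapply(tab, length, integer(1)) > 1]
  if (!length(tab)) stop("no contig carries more than one marker")
  miss <- missing_code(gm$population_type)
  ncmp <- 0L; nevt <- 0L
  flip <- function(x, st) {
    sw <- switch(st,
                 f2 = c(A = "B", H = "H", B = "A"),
                 hkxhk = c(hh = "kk", hk = "hk", kk = "hh"),
                 lmxll = c(ll = "lm", lm = "ll"),
                 nnxnp = c(nn = "np", np = "nn"))
    unname(sw[x])
  }
  for (ms in tab) {
    prs <- utils::combn(ms, 2)
    for (k in seq_len(ncol(prs))) {
      a <- gm$calls[prs[1, k], ]; b <- gm$calls[prs[2, k], ]
      st <- mk$seg_type[match(prs[1, k], mk$marker_id)]
      st2 <- mk$seg_type[match(prs[2, k], mk$marker_id)]
      if (st != st2) next  # differently-typed markers are not comparable
      ok <- a != miss & b != miss
      if (!any(ok)) next
      d1 <- sum(a[ok] != b[ok])
      d2 <- sum(a[ok] != flip(b, st)[ok])
      ncmp <- ncmp + sum(ok)
      nevt <- nevt + min(d1, d2)
    }
  }
  list(n_comparisons = ncmp, n_events = nevt,
       error_rate_pct = 100 * nevt / ncmp)
}

#' @export
print.genetic_map <- function(x, ...) {
  lgs <- unique(x$lg)
  cat("genetic_map:", length(lgs), "linkage group(s),", nrow(x),
      "markers (", sum(x$role == "framework"), "framework /",
      sum(x$role == "accessory"), "accessory )\n")
  spans <- tapply(x$pos_cM, x$lg, function(p) max(p) - min(p))
  cat("  total length:", round(sum(spans), 1), "cM\n")
  invisible(x)
}
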
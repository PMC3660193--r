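#' Specify a mapping cross
#'
#' Two designs are supported: \code{"CP"}, an outbred full-sib family from
#' two distinct, partially heterozygous parents analysed under the two-way
#' pseudo-testcross strategy, and \code{"F2_SELF"}, a selfed F2 from a single
#' heterozygous (hybrid) parent in which every informative marker segregates
#' 1:2:1.
#'
#' Parent haplotypes are given as 2 x n_marker character matrices (rows =
#' the two phased haplotypes, columns named by marker id). For the selfed
#' design, haplotype 1 is by convention inherited from the first grandparent
#' and haplotype 2 from the second; the \code{grandparents} labels let
#' downstream transmission analysis name the origin of a deficient allele.
#'
#' @param design \code{"CP"} or \code{"F2_SELF"}.
#' @param parents for CP a list of two matrices \code{list(mother=, father=)};
#'   for F2_SELF a list of one matrix \code{list(parent=)}.
#' @param n_offspring number of surviving offspring to simulate.
#' @param seed integer root seed; all randomness in [simulate_cross()] flows
#'   from it.
#' @param grandparents length-2 character vector labelling the origin of the
#'   selfed parent's two haplotypes (ignored for CP).
#' @return An object of class \code{cross_design}.
#' @export
cross_design <- function(design = c("CP", "F2_SELF"), parents, n_offspring,
                         seed = 1L,
                         grandparents = c("grandparent1", "grandparent2")) {
  design <- match.arg(design)
  stopifnot(n_offspring >= 1, is.list(parents))
  chk <- function(h) {
    stopifnot(is.matrix(h), nrow(h) == 2, !is.null(colnames(h)))
    h
  }
  if (design == "CP") {
    if (length(parents) != 2)
      stop("CP design requires two distinct parents")
    parents <- lapply(parents, chk)
    if (is.null(names(parents))) names(parents) <- c("mother", "father")
    if (identical(parents[[1]], parents[[2]]))
      stop("CP design requires two distinct parents")
  } else {
    if (length(parents) != 1)
      stop("F2_SELF design requires exactly one selfed parent")
    parents <- lapply(parents, chk)
    if (is.null(names(parents))) names(parents) <- "parent"
  }
  structure(list(design = design, parents = parents,
                 n_offspring = as.integer(n_offspring),
                 seed = as.integer(seed),
                 grandparents = grandparents),
            class = "cross_design")
}

#' Fully informative selfed-F2 parent haplotypes
#'
#' Builds the phased haplotypes of an F1 hybrid heterozygous at every marker
#' of the map: haplotype 1 carries allele \code{alleles[1]} throughout
#' (first grandparent), haplotype 2 allele \code{alleles[2]}.
#'
#' @param map a [true_map()].
#' @param alleles length-2 allele labels.
#' @return 2 x n_marker character matrix.
#' @export
f2_parent <- function(map, alleles = c("a", "b")) {
  ids <- map$markers$marker_id
  h <- rbind(rep(alleles[1], length(ids)), rep(alleles[2], length(ids)))
  colnames(h) <- ids
  h
}

#' Parent haplotypes for a CP pseudo-testcross family
#'
#' Assigns each marker deterministically (interleaved, proportional) to one
#' of three informativeness classes: maternal testcross (mother heterozygous,
#' father homozygous; offspring 1:1), paternal testcross, or intercross
#' (both parents heterozygous; offspring 1:2:1). The default mix reflects a
#' typical SNP assay on an outbred family, where 1:1 markers dominate.
#'
#' @param map a [true_map()].
#' @param prop named numeric proportions for classes \code{mat}, \code{pat},
#'   \code{both}; normalized internally.
#' @return list of two haplotype matrices \code{mother}, \code{father}.
#' @export
cp_parents <- function(map, prop = c(mat = 0.33, pat = 0.40, both = 0.27)) {
  ids <- map$markers$marker_id
  n <- length(ids)
  prop <- prop / sum(prop)
  # deterministic interleaving: class with largest deficit takes next marker
  cls <- character(n)
  got <- c(mat = 0, pat = 0, both = 0)
  for (i in seq_len(n)) {
    deficit <- prop * i - got
    k <- names(which.max(deficit))
    cls[i] <- k
    got[k] <- got[k] + 1
  }
  mom <- rbind(rep("a", n), rep("a", n))
  dad <- rbind(rep("a", n), rep("a", n))
  mom[2, cls %in% c("mat", "both")] <- "b"
  dad[2, cls %in% c("pat", "both")] <- "b"
  colnames(mom) <- colnames(dad) <- ids
  list(mother = mom, father = dad)
}

# One meiosis for one parent. Crossovers per linkage group are drawn as a
# count-location process on the modifier-warped distance scale: count ~
# Poisson(effective length in Morgans), locations uniform on the warped
# scale (no interference). With interference_nu > 1 a gamma-renewal chiasma
# process (shape nu, rate 2*nu per Morgan, thinned 1/2) is used instead.
# Returns transmitted alleles plus strand origin at optional query loci.
simulate_gamete <- function(parent, map, parent_label = "shared",
                            query = NULL, interference_nu = 1) {
  mk <- map$markers
  if (!all(mk$marker_id %in% colnames(parent)))
    stop("parent haplotypes do not cover all markers on the map")
  alleles <- character(nrow(mk))
  names(alleles) <- mk$marker_id
  n_xo <- integer(nrow(map$linkage_groups))
  names(n_xo) <- map$linkage_groups$lg
  qstrand <- if (!is.null(query)) integer(nrow(query)) else NULL

  for (gi in seq_len(nrow(map$linkage_groups))) {
    g <- map$linkage_groups$lg[gi]
    wf <- warp_fun(parent_track(map, parent_label, g))
    Lm <- wf$total / 100  # effective length in Morgans
    if (interference_nu == 1) {
      k <- stats::rpois(1, Lm)
      xw <- if (k > 0) sort(stats::runif(k, 0, wf$total)) else numeric(0)
    } else {
      # gamma-renewal chiasma process, thinned 1/2
      pts <- numeric(0); pos <- 0
      repeat {
        pos <- pos + stats::rgamma(1, shape = interference_nu,
                                   rate = 2 * interference_nu) * 100
        if (pos > wf$total) break
        pts <- c(pts, pos)
      }
      keep <- stats::runif(length(pts)) < 0.5
      xw <- pts[keep]
    }
    xo <- wf$backward(xw)
    n_xo[g] <- length(xo)
    start <- sample.int(2, 1)
    idx <- mk$lg == g
    strand <- 1 + (start - 1 + findInterval(mk$pos_cM[idx], xo)) %% 2
    ids <- mk$marker_id[idx]
    alleles[ids] <- parent[cbind(strand, match(ids, colnames(parent)))]
    if (!is.null(query)) {
      qi <- query$lg == g
      if (any(qi))
        qstrand[qi] <- 1 + (start - 1 + findInterval(query$pos_cM[qi], xo)) %% 2
    }
  }
  list(alleles = alleles, n_xo = n_xo, query_strand = qstrand)
}

# Marker informativeness classes for a CP cross, from parental haplotypes.
cp_seg_types <- function(mother, father, marker_ids) {
  vapply(marker_ids, function(m) {
    mo <- mother[, m]; fa <- father[, m]
    mhet <- mo[1] != mo[2]; fhet <- fa[1] != fa[2]
    if (mhet && !fhet) "lmxll"
    else if (!mhet && fhet) "nnxnp"
    else if (mhet && fhet) {
      if (setequal(mo, fa)) "hkxhk" else "uninformative"
    } else "uninformative"
  }, character(1))
}

#' Legal genotype codes for a marker segregation type
#'
#' @param seg_type one of \code{"f2"}, \code{"lmxll"}, \code{"nnxnp"},
#'   \code{"hkxhk"}.
#' @return character vector of legal (non-missing) codes.
#' @export
legal_codes <- function(seg_type) {
  switch(seg_type,
         f2 = c("A", "H", "B"),
         lmxll = c("ll", "lm"),
         nnxnp = c("nn", "np"),
         hkxhk = c("hh", "hk", "kk"),
         uninformative = character(0),
         stop("unknown segregation type: ", seg_type))
}

#' Missing-call symbol for a population type
#' @param population_type \code{"F2"} or \code{"CP"}.
#' @return single character.
#' @export
missing_code <- function(population_type)
  if (population_type == "F2") "U" else "--"

#' Simulate a mapping population
#'
#' Forward simulation of \code{n_offspring} surviving offspring: each
#' offspring is formed from two independent gametes (two meioses of the same
#' parent under selfing). If the map carries a viability locus, each
#' conceived offspring survives with probability equal to the fitness of its
#' genotype class at that locus (rejection sampling until enough survivors),
#' which generates clustered segregation distortion around the locus.
#' Surviving genotypes are then corrupted: each call is replaced by a random
#' different legal code with probability \code{error_rate} and masked as
#' missing with probability \code{missing_rate}.
#'
#' The defaults mirror a high-quality SNP-array study: a genotyping error
#' rate of 0.17\% (the discordance rate measured between same-contig SNPs on
#' such arrays) and 2\% missing calls.
#'
#' @param design a [cross_design()].
#' @param map a [true_map()]; the viability locus and per-parent rate
#'   modifier tracks live here.
#' @param error_rate per-call probability of a random wrong (legal) code.
#' @param missing_rate per-call probability of masking as missing.
#' @param interference_nu crossover interference parameter (gamma-renewal
#'   shape); 1 = no interference (Poisson count-location), the default.
#' @return A \code{genotype_matrix}: list with \code{population_type}
#'   ("F2" or "CP"), \code{calls} (marker x individual character matrix),
#'   \code{markers} (metadata: lg, true position, contig, segregation type),
#'   and a \code{truth} record (pre-corruption calls, crossover counts per
#'   offspring and linkage group, number of conceptions needed).
#' @examples
#' tm <- grid_true_map(n_lg = 1, length_cM = 50, spacing_cM = 10)
#' cd <- cross_design("F2_SELF", list(parent = f2_parent(tm)),
#'                    n_offspring = 50, seed = 42)
#' gm <- simulate_cross(cd, tm)
#' gm
#' @export
simulate_cross <- function(design, map, error_rate = 0.0017,
                           missing_rate = 0.02, interference_nu = 1) {
  stopifnot(inherits(design, "cross_design"), inherits(map, "true_map"))
  set.seed(design$seed)
  mk <- map$markers
  n <- design$n_offspring
  vl <- map$viability_locus
  query <- if (!is.null(vl))
    data.frame(lg = vl$lg, pos_cM = vl$pos_cM) else NULL

  if (design$design == "F2_SELF") {
    par1 <- par2 <- design$parents[[1]]
    lab1 <- lab2 <- names(design$parents)[1]
    if (any(par1[1, mk$marker_id] == par1[2, mk$marker_id]))
      stop("F2_SELF parent must be heterozygous at every map marker")
    seg <- stats::setNames(rep("f2", nrow(mk)), mk$marker_id)
    pop <- "F2"
  } else {
    par1 <- design$parents$mother; par2 <- design$parents$father
    lab1 <- "mother"; lab2 <- "father"
    seg <- cp_seg_types(par1, par2, mk$marker_id)
    pop <- "CP"
  }

  calls <- matrix(NA_character_, nrow(mk), n,
                  dimnames = list(mk$marker_id,
                                  sprintf("ind%04d", seq_len(n))))
  xo <- matrix(0L, n, nrow(map$linkage_groups),
               dimnames = list(colnames(calls), map$linkage_groups$lg))
  vclass <- character(n)
  n_attempts <- 0L
  i <- 1L
  while (i <= n) {
    n_attempts <- n_attempts + 1L
    if (n_attempts > 1e6 * n)
      stop("viability selection rejected too many conceptions")
    g1 <- simulate_gamete(par1, map, lab1, query, interference_nu)
    g2 <- simulate_gamete(par2, map, lab2, query, interference_nu)
    if (!is.null(vl)) {
      cl <- paste0(sort(c(g1$query_strand, g2$query_strand)), collapse = "")
      fit <- vl$fitness[[cl]]
      if (stats::runif(1) > fit) next
      vclass[i] <- cl
    }
    calls[, i] <- encode_offspring(g1$alleles, g2$alleles, par1, par2, seg,
                                   design$design, mk$marker_id)
    xo[i, ] <- g1$n_xo + g2$n_xo
    i <- i + 1L
  }

  truth_calls <- calls
  # genotyping error: symmetric random substitution among legal codes
  if (error_rate > 0) {
    for (m in seq_len(nrow(calls))) {
      lc <- legal_codes(seg[m])
      if (length(lc) < 2) next
      hit <- which(stats::runif(n) < error_rate)
      for (j in hit)
        calls[m, j] <- sample(setdiff(lc, calls[m, j]), 1)
    }
  }
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(length(calls)) < missing_rate,
                   nrow(calls), ncol(calls))
    calls[mask] <- missing_code(pop)
  }

  markers <- data.frame(marker_id = mk$marker_id, lg = mk$lg,
                        pos_cM = mk$pos_cM, contig_id = mk$contig_id,
                        seg_type = unname(seg[mk$marker_id]),
                        stringsAsFactors = FALSE)
  structure(list(population_type = pop, calls = calls, markers = markers,
                 design = design,
                 truth = list(calls = truth_calls, crossovers = xo,
                              viability_class = vclass,
                              n_attempts = n_attempts),
                 error_rate = error_rate, missing_rate = missing_rate),
            class = "genotype_matrix")
}

# Translate one offspring's transmitted alleles into genotype call codes.
encode_offspring <- function(a1, a2, par1, par2, seg, design, ids) {
  out <- character(length(ids))
  for (k in seq_along(ids)) {
    m <- ids[k]
    st <- seg[[m]]
    if (st == "f2") {
      nb <- (a1[m] == par1[2, m]) + (a2[m] == par1[2, m])
      out[k] <- c("A", "H", "B")[nb + 1]
    } else if (st == "lmxll") {
      out[k] <- if (a1[m] == par1[2, m]) "lm" else "ll"
    } else if (st == "nnxnp") {
      out[k] <- if (a2[m] == par2[2, m]) "np" else "nn"
    } else if (st == "hkxhk") {
      nb <- (a1[m] == par1[2, m]) + (a2[m] == par2[2, m])
      out[k] <- c("hh", "hk", "kk")[nb + 1]
    } else {
      out[k] <- "--"
    }
  }
  out
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix (", x$population_type, "): ",
      nrow(x$calls), " markers x ", ncol(x$calls), " offspring\n", sep = "")
  tab <- table(x$markers$seg_type)
  cat("  segregation types:",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  miss <- mean(x$calls == missing_code(x$population_type))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Genotype-class counts for one marker
#'
#' Tabulates non-missing calls in the order of [legal_codes()] for the
#' marker's segregation type, together with its expected Mendelian ratio.
#'
#' @param gm a \code{genotype_matrix}.
#' @param marker_id marker to tabulate.
#' @return list(counts, ratio, seg_type).
#' @export
geno_counts <- function(gm, marker_id) {
  st <- gm$markers$seg_type[match(marker_id, gm$markers$marker_id)]
  if (is.na(st)) stop("unknown marker: ", marker_id)
  lc <- legal_codes(st)
  cl <- gm$calls[marker_id, ]
  counts <- vapply(lc, function(code) sum(cl == code), integer(1))
  ratio <- if (length(lc) == 3) c(1, 2, 1) else c(1, 1)
  list(counts = counts, ratio = ratio, seg_type = st)
}
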
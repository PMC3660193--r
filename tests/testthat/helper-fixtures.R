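# Shared fixture builders and independent oracles for the test suite.

# Single-LG true map with markers at given positions.
line_map <- function(pos, length_cM = max(pos), lg = "LG1",
                     contig = NULL, ...) {
  true_map(
    data.frame(lg = lg, length_cM = length_cM),
    data.frame(marker_id = sprintf("M%02d", seq_along(pos)), lg = lg,
               pos_cM = pos,
               contig_id = if (is.null(contig))
                 sprintf("C%02d", seq_along(pos)) else contig),
    ...)
}

# Clean selfed-F2 genotype matrix (no error/missing unless asked).
sim_f2 <- function(map, n, seed, error_rate = 0, missing_rate = 0, ...) {
  cd <- cross_design("F2_SELF", list(parent = f2_parent(map)), n,
                     seed = seed,
                     grandparents = c("Landes", "Corsica"))
  simulate_cross(cd, map, error_rate, missing_rate, ...)
}

sim_cp <- function(map, n, seed, error_rate = 0, missing_rate = 0,
                   prop = c(mat = 0.4, pat = 0.4, both = 0.2)) {
  cd <- cross_design("CP", cp_parents(map, prop), n, seed = seed)
  simulate_cross(cd, map, error_rate, missing_rate)
}

# Plain data.frame genetic map (bypassing estimation) for fixture layouts.
fixture_map <- function(lg, marker_id, pos_cM, role = "framework") {
  out <- data.frame(lg = lg, marker_id = marker_id, pos_cM = pos_cM,
                    role = role, nearest_framework = NA_character_,
                    attach_dist_cM = NA_real_, attach_lod = NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("genetic_map", "data.frame")
  out
}

# Haldane map function: the closed-form oracle for the no-interference
# crossover process the simulator uses.
haldane_rf <- function(cM) 0.5 * (1 - exp(-cM / 50))

# Independent F2 3x3 cell probabilities (coupling), written from first
# principles for oracle use; deliberately separate from the package code.
oracle_f2_probs <- function(r) {
  s <- 1 - r
  gam <- c(AB = s / 2, ab = s / 2, Ab = r / 2, aB = r / 2)
  cls <- matrix(0, 3, 3)  # rows geno at locus1 (aa,Aa,AA->idx), cols locus2
  idx <- function(nA) nA + 1
  for (g1 in names(gam)) for (g2 in names(gam)) {
    a1 <- (substr(g1, 1, 1) == "A") + (substr(g2, 1, 1) == "A")
    a2 <- (substr(g1, 2, 2) == "B") + (substr(g2, 2, 2) == "B")
    cls[idx(a1), idx(a2)] <- cls[idx(a1), idx(a2)] + gam[[g1]] * gam[[g2]]
  }
  cls
}

# Grid-search MLE of the F2 recombination fraction (both phases), used as
# the independent optimum against which the EM is checked.
oracle_f2_grid <- function(tab, grid = seq(1e-4, 0.5, by = 1e-4)) {
  ll <- function(r) {
    p <- oracle_f2_probs(r)
    sum(tab[p > 0] * log(p[p > 0]))
  }
  # repulsion phase = coupling with r -> 1 - r
  llr <- function(r) {
    p <- oracle_f2_probs(1 - r)
    sum(tab[p > 0] * log(p[p > 0]))
  }
  lc <- vapply(grid, ll, numeric(1))
  lr <- vapply(grid, llr, numeric(1))
  if (max(lc) >= max(lr)) grid[which.max(lc)] else grid[which.max(lr)]
}

# Two-stage Sheather-Jones direct plug-in bandwidth, hand-coded as an
# independent reference for the stats::bw.SJ(method = "dpi") call.
oracle_sj_dpi <- function(x) {
  n <- length(x)
  sd_x <- stats::sd(x)
  phi4 <- function(u) (u^4 - 6 * u^2 + 3) * stats::dnorm(u)
  phi6 <- function(u) (u^6 - 15 * u^4 + 45 * u^2 - 15) * stats::dnorm(u)
  psi_hat <- function(g, deriv_fun, r) {
    d <- outer(x, x, "-") / g
    sum(deriv_fun(d)) / (n^2 * g^(r + 1))
  }
  psi8_ns <- 105 / (32 * sqrt(pi) * sd_x^9)
  g6 <- (-2 * (-15 / sqrt(2 * pi)) / (n * psi8_ns))^(1 / 9)
  psi6 <- psi_hat(g6, phi6, 6)
  g4 <- (-2 * (3 / sqrt(2 * pi)) / (n * psi6))^(1 / 7)
  psi4 <- psi_hat(g4, phi4, 4)
  (1 / (2 * sqrt(pi) * n * psi4))^(1 / 5)
}

# Exact paired signed-rank p-value by enumerating all sign assignments.
oracle_wilcoxon_exact <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  mu <- n * (n + 1) / 4
  # two-sided: as extreme or more, measured from the null centre
  mean(abs(v_all - mu) >= abs(v_obs - mu))
}

# Genotype matrix engineered to hold exactly `comparisons` same-contig
# call comparisons and `events` discordances: contigs carry marker pairs
# with identical calls except for `events` single-call flips; one partial
# pair absorbs the remainder of comparisons via missing calls.
make_contig_gm <- function(n_ind, comparisons, events) {
  full <- comparisons %/% n_ind
  rem <- comparisons %% n_ind
  npair <- full + (rem > 0)
  stopifnot(events <= full)
  base <- rep(c("A", "H", "B"), length.out = n_ind)
  calls <- matrix(NA_character_, 2 * npair, n_ind)
  ids <- character(2 * npair)
  contigs <- character(2 * npair)
  for (p in seq_len(npair)) {
    m1 <- base
    m2 <- base
    if (p <= events) m2[1] <- ifelse(m2[1] == "A", "H", "A")
    if (p == npair && rem > 0) m2[seq(rem + 1, n_ind)] <- "U"
    calls[2 * p - 1, ] <- m1
    calls[2 * p, ] <- m2
    ids[c(2 * p - 1, 2 * p)] <- sprintf("ctg%04d_snp%d", p, 1:2)
    contigs[c(2 * p - 1, 2 * p)] <- sprintf("ctg%04d", p)
  }
  rownames(calls) <- ids
  colnames(calls) <- sprintf("ind%04d", seq_len(n_ind))
  structure(list(
    population_type = "F2", calls = calls,
    markers = data.frame(marker_id = ids, lg = "LG1",
                         pos_cM = NA_real_, contig_id = contigs,
                         seg_type = "f2", stringsAsFactors = FALSE),
    design = NULL, truth = NULL,
    error_rate = NA_real_, missing_rate = NA_real_),
    class = "genotype_matrix")
}
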
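#' Default pipeline configuration
#'
#' The demo configuration simulates the two mating designs side by side:
#' a selfed F2 and an outbred CP full-sib family from the same genome,
#' with a semi-lethal viability locus segregating only upon inbreeding and
#' a local recombination-rate modifier shared by all parents. Sample sizes
#' follow a typical SNP-array mapping study of a conifer full-sib design
#' (69 F2 and 83 CP offspring genotyped; 380 F2s in the validation
#' cohort).
#'
#' @return nested list accepted by [run_pipeline()].
#' @export
default_config <- function() {
  list(
    seed = 1L,
    map = list(n_lg = 3, length_cM = 120, spacing_cM = 4),
    viability = list(lg = "LG02", pos_cM = 60,
                     fitness = c("11" = 1, "12" = 1, "22" = 0.1)),
    modifiers = list(list(lg = "LG03", start = 40, end = 60,
                          multiplier = 0.25)),
    f2 = list(n_offspring = 69, n_validation = 380),
    cp = list(n_offspring = 83),
    noise = list(error_rate = 0.0017, missing_rate = 0.02),
    analysis = list(alpha = 0.01, lod_min = 3, min_cluster = 3,
                    max_gap_cM = 10, coverage_X = 30)
  )
}

req <- function(cfg, key) {
  parts <- strsplit(key, "\\$")[[1]]
  for (p in parts) {
    if (is.null(cfg[[p]]))
      stop("configuration error: missing key '", key, "'")
    cfg <- cfg[[p]]
  }
  cfg
}

#' Run the full simulate-map-analyse pipeline
#'
#' Stages: simulate the F2 and CP populations; estimate genetic maps
#' (F2 map plus maternal and paternal CP maps); per-marker segregation
#' tests and SDR detection on each; inbred/outbred contrast and
#' larger-cohort validation of F2 SDR candidates; genome length/coverage;
#' recombination landscape per map; recombination-rate comparison between
#' the F2 and CP maps. All outputs are written as TSV under
#' \code{out_dir}; the returned list carries the in-memory objects. The
#' run is deterministic given \code{config$seed}.
#'
#' @param config nested list (see [default_config()]) or path to a YAML
#'   file with the same structure.
#' @param out_dir output directory (created if needed); \code{NULL}
#'   disables file output.
#' @param seed optional override of \code{config$seed}.
#' @return list with elements \code{truemap, f2, cp, maps, seg, sdr,
#'   coverage, landscape, comparison, summary}.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  root_seed <- as.integer(req(config, "seed"))

  mods <- NULL
  if (!is.null(config$modifiers)) {
    mods <- do.call(rbind, lapply(config$modifiers, function(m)
      data.frame(lg = m$lg, start = m$start, end = m$end,
                 multiplier = m$multiplier)))
  }
  vl <- NULL
  if (!is.null(config$viability)) {
    fit <- unlist(req(config, "viability$fitness"))
    vl <- list(lg = req(config, "viability$lg"),
               pos_cM = req(config, "viability$pos_cM"), fitness = fit)
  }
  tm_f2 <- grid_true_map(req(config, "map$n_lg"),
                         req(config, "map$length_cM"),
                         req(config, "map$spacing_cM"),
                         rate_modifiers =
                           if (is.null(mods)) NULL else list(shared = mods),
                         viability_locus = vl)
  # outbreeding does not expose the recessive viability allele
  tm_cp <- grid_true_map(req(config, "map$n_lg"),
                         req(config, "map$length_cM"),
                         req(config, "map$spacing_cM"),
                         rate_modifiers =
                           if (is.null(mods)) NULL else list(shared = mods))

  err <- req(config, "noise$error_rate")
  mis <- req(config, "noise$missing_rate")
  cd_f2 <- cross_design("F2_SELF", list(parent = f2_parent(tm_f2)),
                        req(config, "f2$n_offspring"), seed = root_seed,
                        grandparents = c("grandmaternal", "grandpaternal"))
  gm_f2 <- simulate_cross(cd_f2, tm_f2, err, mis)
  cd_val <- cross_design("F2_SELF", list(parent = f2_parent(tm_f2)),
                         req(config, "f2$n_validation"),
                         seed = root_seed + 1L,
                         grandparents = c("grandmaternal", "grandpaternal"))
  gm_val <- simulate_cross(cd_val, tm_f2, err, mis)
  cd_cp <- cross_design("CP", cp_parents(tm_cp),
                        req(config, "cp$n_offspring"),
                        seed = root_seed + 2L)
  gm_cp <- simulate_cross(cd_cp, tm_cp, err, mis)

  an <- req(config, "analysis")
  map_f2 <- build_map(gm_f2, lod_min = an$lod_min)
  map_g2f <- build_map(gm_cp, parent = "mother", lod_min = an$lod_min)
  map_g2m <- build_map(gm_cp, parent = "father", lod_min = an$lod_min)

  seg_f2 <- seg_test_all(gm_f2, an$alpha)
  seg_cp <- seg_test_all(gm_cp, an$alpha)
  seg_g2f <- seg_cp[seg_cp$marker_id %in% map_g2f$marker_id, ]
  seg_g2m <- seg_cp[seg_cp$marker_id %in% map_g2m$marker_id, ]

  sdr_f2 <- detect_sdr(map_f2, seg_f2[seg_f2$marker_id %in% map_f2$marker_id, ],
                       an$min_cluster, an$max_gap_cM)
  cand <- contrast_pedigrees(sdr_f2$regions, map_f2, map_g2f, map_g2m,
                             seg_g2f, seg_g2m)
  validated <- if (nrow(cand)) {
    do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
      v <- validate_sdr(cand[i, ], gm_val, an$alpha)
      v$stage <- classify_stage(
        female = any(seg_g2f$distorted &
                       seg_g2f$marker_id %in% strsplit(v$members, ",")[[1]]),
        male = any(seg_g2m$distorted &
                     seg_g2m$marker_id %in% strsplit(v$members, ",")[[1]]),
        zygote = v$status == "validated")
      if (v$status == "validated") {
        to <- transmission_origin(gm_val, strsplit(v$members, ",")[[1]],
                                  an$alpha)
        v$origin <- to$origin
      }
      v
    }))
  } else cand

  cov <- list(F2 = coverage_stats(map_f2, X = an$coverage_X),
              G2F = coverage_stats(map_g2f, X = an$coverage_X),
              G2M = coverage_stats(map_g2m, X = an$coverage_X))
  land <- list(F2 = landscape_profile(map_f2, alpha = an$alpha),
               G2F = landscape_profile(map_g2f, alpha = an$alpha),
               G2M = landscape_profile(map_g2m, alpha = an$alpha))

  comparison <- tryCatch({
    paired <- build_paired_rf(gm_f2, gm_cp, map_f2,
                              segA = seg_f2, segB = seg_cp,
                              parentB = "mother")
    compare_recombination(paired)
  }, error = function(e) {
    message("comparison stage skipped: ", conditionMessage(e))
    NULL
  })

  summary <- data.frame(
    quantity = c("f2_markers_mapped", "f2_map_length_cM",
                 "g2f_map_length_cM", "g2m_map_length_cM",
                 "f2_sdr_candidates", "f2_sdr_validated",
                 "f2_coldspots", "f2_hotspots"),
    value = c(nrow(map_f2), round(sum(lg_spans(map_f2)), 1),
              round(sum(lg_spans(map_g2f)), 1),
              round(sum(lg_spans(map_g2m)), 1),
              nrow(cand),
              if (nrow(cand)) sum(validated$status == "validated") else 0,
              sum(land$F2$intervals$kind == "coldspot"),
              sum(land$F2$intervals$kind == "hotspot")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_genotypes(gm_f2, file.path(out_dir, "genotypes_f2.tsv"))
    write_genotypes(gm_cp, file.path(out_dir, "genotypes_cp.tsv"))
    write_map(map_f2, file.path(out_dir, "map_f2.tsv"))
    write_map(map_g2f, file.path(out_dir, "map_g2f.tsv"))
    write_map(map_g2m, file.path(out_dir, "map_g2m.tsv"))
    utils::write.table(seg_f2, file.path(out_dir, "segtests_f2.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(validated, file.path(out_dir, "sdr_f2.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (nm in names(land))
      utils::write.table(land[[nm]]$windows,
                         file.path(out_dir, paste0("landscape_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(summary, file.path(out_dir, "summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  list(truemap = tm_f2, f2 = gm_f2, f2_validation = gm_val, cp = gm_cp,
       maps = list(F2 = map_f2, G2F = map_g2f, G2M = map_g2m),
       seg = list(F2 = seg_f2, G2F = seg_g2f, G2M = seg_g2m),
       sdr = list(detected = sdr_f2, candidates = cand,
                  validated = validated),
       coverage = cov, landscape = land, comparison = comparison,
       summary = summary)
}
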
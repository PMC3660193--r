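#' Write a genotype matrix to disk
#'
#' Two dialects: \code{"tsv"} (the package's native table: a
#' \code{# population_type=} header line, then columns \code{marker_id, lg,
#' contig_id, seg_type} followed by one column per individual) and
#' \code{"joinmap_loc"} (a JoinMap-style \code{.loc} export with
#' \code{name/popt/nloc/nind} header and per-locus code lines). The TSV
#' dialect round-trips losslessly through [read_genotypes()].
#'
#' @param gm a \code{genotype_matrix}.
#' @param path output file.
#' @param dialect \code{"tsv"} or \code{"joinmap_loc"}.
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(gm, path, dialect = c("tsv", "joinmap_loc")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# population_type=", gm$population_type), con)
    df <- cbind(gm$markers[, c("marker_id", "lg", "contig_id", "seg_type")],
                as.data.frame(gm$calls, stringsAsFactors = FALSE))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("name = simulated",
                 paste0("popt = ", gm$population_type),
                 paste0("nloc = ", nrow(gm$calls)),
                 paste0("nind = ", ncol(gm$calls))), con)
    for (i in seq_len(nrow(gm$calls))) {
      st <- gm$markers$seg_type[i]
      calls <- gm$calls[i, ]
      if (gm$population_type == "F2") {
        code <- c(A = "a", H = "h", B = "b", U = "-")[calls]
        writeLines(paste(c(gm$markers$marker_id[i], code),
                         collapse = " "), con)
      } else {
        writeLines(paste(c(gm$markers$marker_id[i],
                           paste0("<", st, ">"), calls),
                         collapse = " "), con)
      }
    }
  }
  invisible(path)
}

#' Read a genotype matrix written by [write_genotypes()]
#'
#' Strict validation: the population-type header must be present, every
#' call must be a legal code (or the missing symbol) for its marker's
#' segregation type, and marker ids must be unique; violations are
#' reported with the offending line number.
#'
#' @param path file in the \code{"tsv"} dialect.
#' @return a \code{genotype_matrix} (without a simulation truth record).
#' @export
read_genotypes <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# population_type=(F2|CP)$", first))
    stop("line 1: missing or malformed '# population_type=' header")
  pop <- sub("^# population_type=", "", first)
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                          colClasses = "character",
                          check.names = FALSE)
  need <- c("marker_id", "lg", "contig_id", "seg_type")
  if (!all(need %in% names(df)))
    stop("line 2: header must start with ",
         paste(need, collapse = ", "))
  if (anyDuplicated(df$marker_id)) {
    dup <- which(duplicated(df$marker_id))[1]
    stop("line ", dup + 2, ": duplicate marker id '", df$marker_id[dup], "'")
  }
  ind <- setdiff(names(df), need)
  calls <- as.matrix(df[, ind, drop = FALSE])
  rownames(calls) <- df$marker_id
  miss <- missing_code(pop)
  for (i in seq_len(nrow(df))) {
    legal <- c(legal_codes(df$seg_type[i]), miss)
    bad <- !calls[i, ] %in% legal
    if (any(bad))
      stop("line ", i + 2, ": illegal call code '",
           calls[i, which(bad)[1]], "' for marker ", df$marker_id[i])
  }
  markers <- data.frame(marker_id = df$marker_id, lg = df$lg,
                        pos_cM = NA_real_, contig_id = df$contig_id,
                        seg_type = df$seg_type, stringsAsFactors = FALSE)
  structure(list(population_type = pop, calls = calls, markers = markers,
                 design = NULL, truth = NULL,
                 error_rate = NA_real_, missing_rate = NA_real_),
            class = "genotype_matrix")
}

#' Write / read a genetic map as TSV
#'
#' Columns: \code{lg, marker_id, position_cM, role, nearest_framework,
#' attach_dist_cM, attach_lod}. Positions must be sorted (non-decreasing)
#' within each linkage group; the reader validates this and reports the
#' offending line.
#'
#' @param map a \code{genetic_map}.
#' @param path file path.
#' @return \code{write_map}: \code{path} invisibly; \code{read_map}: a
#'   \code{genetic_map}.
#' @export
write_map <- function(map, path) {
  out <- data.frame(lg = map$lg, marker_id = map$marker_id,
                    position_cM = map$pos_cM, role = map$role,
                    nearest_framework = map$nearest_framework,
                    attach_dist_cM = map$attach_dist_cM,
                    attach_lod = map$attach_lod)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("lg", "marker_id", "position_cM", "role")
  if (!all(need %in% names(df)))
    stop("line 1: map header must contain ", paste(need, collapse = ", "))
  if (anyDuplicated(df$marker_id)) {
    dup <- which(duplicated(df$marker_id))[1]
    stop("line ", dup + 1, ": duplicate marker id '", df$marker_id[dup], "'")
  }
  for (g in unique(df$lg)) {
    p <- df$position_cM[df$lg == g]
    if (is.unsorted(p)) {
      i <- which(df$lg == g)[which(diff(p) < 0)[1] + 1]
      stop("line ", i + 1, ": positions not sorted within ", g)
    }
  }
  out <- data.frame(lg = df$lg, marker_id = df$marker_id,
                    pos_cM = df$position_cM, role = df$role,
                    nearest_framework =
                      if ("nearest_framework" %in% names(df))
                        df$nearest_framework else NA_character_,
                    attach_dist_cM =
                      if ("attach_dist_cM" %in% names(df))
                        df$attach_dist_cM else NA_real_,
                    attach_lod = if ("attach_lod" %in% names(df))
                      df$attach_lod else NA_real_,
                    stringsAsFactors = FALSE)
  class(out) <- c("genetic_map", "data.frame")
  out
}

#' Read an anchor table
#'
#' Long-format TSV with columns \code{marker_id, map, lg, position_cM}
#' listing, for each shared marker, its location on each map.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_anchors <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("marker_id", "map", "lg", "position_cM")
  if (!all(need %in% names(df)))
    stop("anchor header must contain ", paste(need, collapse = ", "))
  df
}

#' SNP-assay genotyping QC summary
#'
#' Conversion rate = polymorphic loci / total assayed loci, as a
#' percentage; poor-performance rate likewise. These are the standard
#' figures of merit when an array designed in silico is genotyped on a
#' mapping population.
#'
#' @param n_polymorphic loci yielding usable polymorphic genotypes.
#' @param n_poor loci excluded for poor assay performance.
#' @param n_total loci in the assay.
#' @param n_monomorphic optional count of monomorphic loci.
#' @return list of class \code{assay_qc}: counts plus
#'   \code{conversion_rate_pct} and \code{poor_rate_pct} (one decimal).
#' @examples
#' qc_summary(2264, 2156, 9279)  # conversion 24.4%, poor 23.2%
#' @export
qc_summary <- function(n_polymorphic, n_poor, n_total,
                       n_monomorphic = NA_integer_) {
  stopifnot(n_polymorphic >= 0, n_poor >= 0)
  if (n_total <= 0) stop("total assayed count must be positive")
  if (n_polymorphic + n_poor +
      ifelse(is.na(n_monomorphic), 0, n_monomorphic) > n_total)
    stop("component counts exceed the total")
  structure(list(n_total_assayed = n_total,
                 n_polymorphic = n_polymorphic,
                 n_poor = n_poor, n_monomorphic = n_monomorphic,
                 conversion_rate_pct = round(100 * n_polymorphic / n_total, 1),
                 poor_rate_pct = round(100 * n_poor / n_total, 1)),
            class = "assay_qc")
}

#' @export
print.assay_qc <- function(x, ...) {
  cat(sprintf("assay_qc: %d loci assayed; conversion %.1f%%, poor %.1f%%\n",
              x$n_total_assayed, x$conversion_rate_pct, x$poor_rate_pct))
  invisible(x)
}
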
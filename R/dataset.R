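#' Construct a genotype/phenotype dataset
#'
#' A `gp_dataset` holds aligned records of a single quantitative trait:
#' allele-dosage genotypes coded 0/1/2 (donor-allele count, `NA` = missing
#' call), a phenotype vector, a population label and a 0/1 replicate
#' (evaluation) factor per record.
#'
#' @param ids character vector of record identifiers.
#' @param population character/factor population label per record.
#' @param G numeric matrix, records x markers, entries in \{0, 1, 2\} or `NA`.
#' @param y numeric phenotype per record (trait units), `NA` allowed until
#'   [drop_missing_phenotypes()] has been applied.
#' @param replicate integer 0/1 evaluation factor per record.
#' @param marker_names optional marker identifiers (defaults to `colnames(G)`).
#' @param phenotype_name name of the trait column (metadata only).
#' @return An object of class `gp_dataset`.
#' @export
gp_dataset <- function(ids, population, G, y, replicate = NULL,
                       marker_names = NULL, phenotype_name = "trait") {
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  n <- nrow(G)
  if (is.null(marker_names)) marker_names <- colnames(G)
  if (is.null(marker_names)) marker_names <- sprintf("M%04d", seq_len(ncol(G)))
  colnames(G) <- marker_names
  if (is.null(replicate)) replicate <- rep(0L, n)
  replicate <- as.integer(replicate)
  ids <- as.character(ids)
  population <- as.character(population)
  if (length(population) == 1L) population <- rep(population, n)
  if (length(ids) != n || length(population) != n || length(y) != n ||
      length(replicate) != n) {
    stop("ids, population, y, replicate must all match nrow(G) = ", n)
  }
  if (anyDuplicated(marker_names)) stop("duplicate marker names")
  if (anyDuplicated(paste(ids, replicate, sep = "\r"))) {
    stop("duplicate (id, replicate) pairs")
  }
  ok <- is.na(G) | G %in% c(0, 1, 2)
  if (!all(ok)) stop("genotype dosages must be 0, 1, 2 or missing")
  if (!all(replicate %in% c(0L, 1L))) stop("replicate factor must be 0 or 1")
  structure(list(ids = ids, population = population, G = G,
                 y = as.numeric(y), replicate = replicate,
                 marker_names = marker_names,
                 phenotype_name = phenotype_name),
            class = "gp_dataset")
}

#' @export
print.gp_dataset <- function(x, ...) {
  cat(sprintf("gp_dataset: %d records x %d markers\n", nrow(x$G), ncol(x$G)))
  cat(sprintf("  populations: %s\n",
              paste(unique(x$population), collapse = ", ")))
  cat(sprintf("  trait '%s': %d missing; markers: %d missing calls\n",
              x$phenotype_name, sum(is.na(x$y)), sum(is.na(x$G))))
  invisible(x)
}

#' @export
dim.gp_dataset <- function(x) dim(x$G)

n_records <- function(d) nrow(d$G)

#' Subset the records of a dataset
#'
#' @param d a [gp_dataset()].
#' @param i record (row) index vector.
#' @return The subset `gp_dataset`.
#' @export
subset_records <- function(d, i) {
  gp_dataset(d$ids[i], d$population[i], d$G[i, , drop = FALSE], d$y[i],
             d$replicate[i], d$marker_names, d$phenotype_name)
}

#' Subset the markers of a dataset
#'
#' @param d a [gp_dataset()].
#' @param keep marker names or column indices to retain.
#' @return The subset `gp_dataset`.
#' @export
subset_markers <- function(d, keep) {
  gp_dataset(d$ids, d$population, d$G[, keep, drop = FALSE], d$y,
             d$replicate, phenotype_name = d$phenotype_name)
}

#' Feature matrix presented to the prediction models
#'
#' Markers plus the replicate factor as one extra column (`.replicate`), the
#' form in which every model in the ensemble sees a record.
#'
#' @param d a [gp_dataset()].
#' @return Numeric matrix with `ncol(d$G) + 1` columns.
#' @export
feature_matrix <- function(d) {
  cbind(d$G, .replicate = as.numeric(d$replicate))
}

#' Read a genotype/phenotype CSV
#'
#' Expected header: `id,population,replicate,<markers...>,<phenotypes...>`.
#' Marker columns are identified either by membership in `map` or by
#' `marker_prefix`; empty cells and `NA` in marker columns become missing
#' calls.
#'
#' @param path CSV file path.
#' @param map optional [genetic_map()]; columns found in the map are markers.
#' @param marker_prefix optional string; columns starting with it are markers.
#' @param phenotype trait column to use (default: first non-marker,
#'   non-bookkeeping column).
#' @return A [gp_dataset()]. Marker columns matching `marker_prefix` but
#'   absent from a supplied map are retained with a warning (they cannot be
#'   placed on a circos ring).
#' @export
read_dataset <- function(path, map = NULL, marker_prefix = NULL,
                         phenotype = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("id", "population")
  if (!all(need %in% names(df))) stop("CSV must have 'id' and 'population'")
  cols <- setdiff(names(df), c("id", "population", "replicate"))
  in_map <- if (!is.null(map)) cols %in% map$table$marker else
    rep(FALSE, length(cols))
  by_pref <- if (!is.null(marker_prefix)) startsWith(cols, marker_prefix) else
    rep(FALSE, length(cols))
  is_marker <- in_map | by_pref
  if (!any(is_marker)) stop("no marker columns identified (supply map or marker_prefix)")
  markers <- cols[is_marker]
  if (!is.null(map)) {
    orphan <- markers[!markers %in% map$table$marker]
    if (length(orphan)) {
      warning("marker column(s) not in genetic map (kept, but not placeable ",
              "on circos rings): ", paste(orphan, collapse = ", "))
    }
  }
  phen_cols <- setdiff(cols, markers)
  if (is.null(phenotype)) {
    if (!length(phen_cols)) stop("no phenotype column found")
    phenotype <- phen_cols[1L]
  }
  if (!phenotype %in% names(df)) stop("phenotype column not found: ", phenotype)
  G <- as.matrix(df[, markers, drop = FALSE])
  if (is.character(G)) {
    G[G == ""] <- NA
    storage.mode(G) <- "double"
  }
  repl <- if ("replicate" %in% names(df)) df$replicate else rep(0L, nrow(df))
  gp_dataset(df$id, df$population, G, as.numeric(df[[phenotype]]), repl,
             markers, phenotype)
}

#' Write a dataset back to CSV
#'
#' Inverse of [read_dataset()]; missing calls are written as empty cells.
#'
#' @param d a [gp_dataset()].
#' @param path output CSV path.
#' @export
write_dataset <- function(d, path) {
  df <- data.frame(id = d$ids, population = d$population,
                   replicate = d$replicate, check.names = FALSE)
  df <- cbind(df, as.data.frame(d$G, check.names = FALSE))
  df[[d$phenotype_name]] <- d$y
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Impute missing marker calls with the population-wise modal dosage
#'
#' Markers whose missing fraction exceeds `max_missing_frac` (strictly) are
#' dropped; every remaining missing call is replaced by the most frequent
#' dosage among the non-missing calls of the same population at that marker,
#' ties broken toward the smaller dosage.
#'
#' @param d a [gp_dataset()].
#' @param max_missing_frac markers missing in more than this fraction of
#'   records are excluded (default 0.10).
#' @param per_population logical; compute the exclusion fraction within each
#'   population (`TRUE`, the default, matching one-subpopulation-at-a-time
#'   processing) or over the pooled records.
#' @return A `gp_dataset` with no missing calls.
#' @export
impute_markers <- function(d, max_missing_frac = 0.10, per_population = TRUE) {
  G <- d$G
  pops <- unique(d$population)
  if (per_population && length(pops) > 1L) {
    frac <- do.call(cbind, lapply(pops, function(p) {
      colMeans(is.na(G[d$population == p, , drop = FALSE]))
    }))
    worst <- apply(frac, 1L, max)
  } else {
    worst <- colMeans(is.na(G))
  }
  keep <- worst <= max_missing_frac
  G <- G[, keep, drop = FALSE]
  for (p in pops) {
    rows <- which(d$population == p)
    sub <- G[rows, , drop = FALSE]
    miss_cols <- which(colSums(is.na(sub)) > 0L)
    for (j in miss_cols) {
      v <- sub[, j]
      obs <- v[!is.na(v)]
      if (!length(obs)) {
        stop("marker ", colnames(G)[j], " has no observed call in population ",
             p, "; cannot impute")
      }
      tab <- table(obs)
      # which.max on a table returns the first maximum; names are sorted
      # ascending, so ties already resolve toward the smaller dosage
      mode_val <- as.numeric(names(tab)[which.max(tab)])
      v[is.na(v)] <- mode_val
      G[rows, j] <- v
    }
  }
  gp_dataset(d$ids, d$population, G, d$y, d$replicate,
             phenotype_name = d$phenotype_name)
}

#' Remove records with a missing phenotype
#'
#' @param d a [gp_dataset()].
#' @return The dataset restricted to records with observed `y`, original
#'   order preserved. Errors if nothing survives.
#' @export
drop_missing_phenotypes <- function(d) {
  keep <- which(!is.na(d$y))
  if (!length(keep)) stop("all records have missing phenotypes")
  subset_records(d, keep)
}

#' Windowed LD pruning of markers
#'
#' Greedy pruning on squared Pearson correlation of dosage columns: within
#' each window of `window` consecutive (map-ordered) markers, for every pair
#' with r-squared above `r2_threshold` the later-indexed marker is removed;
#' the window then slides forward by `step` markers. Monomorphic markers have
#' r-squared defined as 0 and are always retained.
#'
#' @param d an imputed [gp_dataset()] (no missing calls), markers in map order.
#' @param window window size in markers (default 30000).
#' @param step slide in markers (default 5).
#' @param r2_threshold prune pairs with r^2 strictly greater (default 0.8).
#' @return The dataset restricted to surviving markers.
#' @export
ld_prune <- function(d, window = 30000, step = 5, r2_threshold = 0.8) {
  G <- d$G
  if (anyNA(G)) stop("ld_prune requires an imputed dataset (no missing calls)")
  p <- ncol(G)
  keep <- rep(TRUE, p)
  sds <- apply(G, 2L, stats::sd)
  if (any(sds == 0)) {
    message("ld_prune: ", sum(sds == 0),
            " monomorphic marker(s) retained (r^2 treated as 0)")
  }
  start <- 1L
  repeat {
    end <- min(start + window - 1L, p)
    idx <- start:end
    live <- idx[keep[idx] & sds[idx] > 0]
    if (length(live) > 1L) {
      r2 <- suppressWarnings(stats::cor(G[, live, drop = FALSE]))^2
      for (a in seq_along(live)) {
        if (!keep[live[a]]) next
        for (b in seq_along(live)) {
          if (b <= a || !keep[live[b]]) next
          if (is.finite(r2[a, b]) && r2[a, b] > r2_threshold) {
            keep[live[b]] <- FALSE
          }
        }
      }
    }
    if (end >= p) break
    start <- start + step
  }
  subset_markers(d, which(keep))
}

#' Concatenate two replicate evaluations of the same population
#'
#' Stacks the records of two evaluations of the same lines; the returned
#' replicate factor is 0 for `d1` rows and 1 for `d2` rows.
#'
#' @param d1,d2 [gp_dataset()] objects sharing marker columns.
#' @return The stacked `gp_dataset`.
#' @export
concat_replicates <- function(d1, d2) {
  if (n_records(d2) == 0L) {
    return(gp_dataset(d1$ids, d1$population, d1$G, d1$y,
                      rep(0L, n_records(d1)), d1$marker_names,
                      d1$phenotype_name))
  }
  if (!identical(d1$marker_names, d2$marker_names)) {
    stop("marker sets differ between the two evaluations")
  }
  gp_dataset(c(d1$ids, d2$ids), c(d1$population, d2$population),
             rbind(d1$G, d2$G), c(d1$y, d2$y),
             c(rep(0L, n_records(d1)), rep(1L, n_records(d2))),
             d1$marker_names, d1$phenotype_name)
}
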
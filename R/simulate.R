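#' Simulate a genetic map
#'
#' Markers are spread uniformly at random along each chromosome (split as
#' evenly as possible across chromosomes) and sorted by position.
#'
#' @param chromosomes number of chromosomes.
#' @param length_cM chromosome length in cM (scalar or one per chromosome).
#' @param p total marker count (>= `chromosomes`).
#' @param seed integer seed.
#' @return A [genetic_map()] with markers named `M0001, M0002, ...` in map
#'   order.
#' @export
simulate_map <- function(chromosomes, length_cM, p, seed = NULL) {
  if (p < chromosomes) stop("need at least one marker per chromosome")
  if (!is.null(seed)) set.seed(seed)
  L <- rep_len(length_cM, chromosomes)
  per <- rep(p %/% chromosomes, chromosomes)
  extra <- p %% chromosomes
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
  chrom <- rep(seq_len(chromosomes), per)
  pos <- unlist(lapply(seq_len(chromosomes), function(c)
    sort(stats::runif(per[c], 0, L[c]))))
  genetic_map(sprintf("M%04d", seq_len(p)), chrom, pos,
              stats::setNames(L, seq_len(chromosomes)))
}

#' Describe a true (simulated) genetic architecture
#'
#' @param causal_idx marker indices (map order) carrying additive effects.
#' @param add_effects additive allele-substitution effects (trait units per
#'   donor-allele copy), one per causal marker.
#' @param epistatic_pairs 2-column matrix of marker index pairs (may be
#'   `NULL`).
#' @param epi_effects interaction effect per pair (applied to the product of
#'   centred dosages).
#' @param h2 target narrow-sense heritability in (0, 1]; 1 means no
#'   environmental noise.
#' @param replicate_effect additive shift of the second evaluation, in units
#'   of the phenotypic SD (default 0.25).
#' @return A list of class `gp_truth`.
#' @export
truth_architecture <- function(causal_idx, add_effects, epistatic_pairs = NULL,
                               epi_effects = NULL, h2 = 0.7,
                               replicate_effect = 0.25) {
  if (length(causal_idx) != length(add_effects)) {
    stop("one additive effect per causal marker")
  }
  if (h2 <= 0 || h2 > 1) stop("h2 must lie in (0, 1]")
  if (!is.null(epistatic_pairs)) {
    epistatic_pairs <- matrix(as.integer(epistatic_pairs), ncol = 2L)
    if (length(epi_effects) != nrow(epistatic_pairs)) {
      stop("one effect per epistatic pair")
    }
  }
  structure(list(causal_idx = as.integer(causal_idx),
                 add_effects = as.numeric(add_effects),
                 epistatic_pairs = epistatic_pairs,
                 epi_effects = as.numeric(epi_effects),
                 h2 = h2, replicate_effect = replicate_effect),
            class = "gp_truth")
}

#' Simulation configuration
#'
#' @param n_ril number of recombinant inbred lines (>= 2).
#' @param map a [genetic_map()] (e.g. from [simulate_map()]).
#' @param seed integer seed.
#' @param population population label for the simulated records.
#' @return A list of class `gp_simconfig`.
#' @export
sim_config <- function(n_ril, map, seed = NULL, population = "SimPop1") {
  if (n_ril < 2) stop("need at least 2 RILs")
  structure(list(n_ril = n_ril, map = map, seed = seed,
                 population = population), class = "gp_simconfig")
}

# one recombinant gamete per individual from haplotype matrices H1, H2
# (n x m, one chromosome), Haldane map function (no interference):
# r = (1 - exp(-2d/100)) / 2 between adjacent markers d cM apart
make_gametes <- function(H1, H2, pos) {
  n <- nrow(H1); m <- ncol(H1)
  start <- sample(c(0L, 1L), n, replace = TRUE)
  if (m == 1L) {
    hap <- matrix(start, n, 1L)
  } else {
    d <- diff(pos)
    r <- 0.5 * (1 - exp(-2 * d / 100))
    sw <- matrix(stats::rbinom(n * (m - 1L), 1L, rep(r, each = n)), n, m - 1L)
    hap <- (matrix(start, n, m) +
              cbind(0L, t(apply(sw, 1L, cumsum)))) %% 2L
  }
  H1 * (hap == 0L) + H2 * (hap == 1L)
}

#' Simulate a BC1S4 recombinant inbred line population
#'
#' Emulates a biparental backcross design: an F1 between the recurrent
#' (allele 0) and donor (allele 1) parent is backcrossed to the recurrent
#' parent, then selfed for four generations, with crossovers drawn from map
#' distances under the Haldane map function. Dosages count donor alleles
#' (0/1/2). The phenotype is the sum of additive effects, epistatic
#' products of centred dosages, a replicate (evaluation) shift, and Gaussian
#' noise scaled so the expected heritability matches the target; every RIL
#' contributes two replicate records (factor 0/1).
#'
#' @param cfg a [sim_config()].
#' @param truth a [truth_architecture()].
#' @return List with `dataset` (a [gp_dataset()]), `truth`, and `components`
#'   (per-record genetic values, noise, replicate shift) for calibration
#'   checks.
#' @export
simulate_ril_population <- function(cfg, truth) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  map <- cfg$map
  n <- cfg$n_ril
  tab <- map$table
  p <- nrow(tab)
  G <- matrix(0L, n, p)
  for (ch in unique(tab$chromosome)) {
    cols <- which(tab$chromosome == ch)
    pos <- tab$position_cM[cols]
    m <- length(cols)
    # F1: one donor haplotype, one recurrent
    F1a <- matrix(1L, n, m); F1b <- matrix(0L, n, m)
    # BC1: recombinant F1 gamete + recurrent-parent gamete
    H1 <- make_gametes(F1a, F1b, pos)
    H2 <- matrix(0L, n, m)
    for (gen in 1:4) {                 # four selfing generations
      H1n <- make_gametes(H1, H2, pos)
      H2n <- make_gametes(H1, H2, pos)
      H1 <- H1n; H2 <- H2n
    }
    G[, cols] <- H1 + H2
  }
  colnames(G) <- tab$marker

  g <- rep(0, n)
  if (length(truth$causal_idx)) {
    g <- g + drop(G[, truth$causal_idx, drop = FALSE] %*% truth$add_effects)
  }
  if (!is.null(truth$epistatic_pairs)) {
    for (q in seq_len(nrow(truth$epistatic_pairs))) {
      i <- truth$epistatic_pairs[q, 1L]; j <- truth$epistatic_pairs[q, 2L]
      g <- g + truth$epi_effects[q] *
        (G[, i] - mean(G[, i])) * (G[, j] - mean(G[, j]))
    }
  }
  var_g <- stats::var(g)
  if (var_g == 0 && length(truth$causal_idx) && truth$h2 > 0) {
    stop("target heritability unreachable: zero genetic variance")
  }
  sd_e <- if (truth$h2 >= 1) 0 else if (var_g > 0) {
    sqrt(var_g * (1 - truth$h2) / truth$h2)
  } else 1
  eps <- stats::rnorm(2L * n, 0, sd_e)
  delta <- truth$replicate_effect * sqrt(var_g + sd_e^2)
  repl <- rep(c(0L, 1L), each = n)
  y <- rep(g, 2L) + eps + delta * repl

  ids <- sprintf("RIL%04d", seq_len(n))
  ds <- gp_dataset(rep(ids, 2L), rep(cfg$population, 2L * n),
                   rbind(G, G), y, repl, tab$marker, "trait")
  list(dataset = ds, truth = truth,
       components = list(g = rep(g, 2L), eps = eps,
                         replicate_shift = delta * repl))
}

#' Realised heritability of a simulated dataset
#'
#' Ratio of the variance of the simulator's true genetic values to the
#' phenotypic variance, computed from the stored components.
#'
#' @param sim a [simulate_ril_population()] result.
#' @return Fraction in [0, 1].
#' @export
realized_h2 <- function(sim) {
  y <- sim$dataset$y
  vg <- stats::var(sim$components$g)
  if (stats::var(y) == 0) return(0)
  vg / stats::var(y)
}

#' Export truth regions as a pseudo-QTL annotation track
#'
#' @param truth a [truth_architecture()].
#' @param map the [genetic_map()] the indices refer to.
#' @param pad_cM padding around each causal marker (default 1 cM).
#' @return An [annotation_track()] named "QTL" (synthetic ground truth).
#' @export
truth_annotation <- function(truth, map, pad_cM = 1) {
  mk <- map$table$marker[truth$causal_idx]
  reg <- extend_regions(map, mk, pad_cM)
  annotation_track("QTL", reg$chromosome, reg$start_cM, reg$end_cM,
                   label = paste0("trueQTL_", mk), pathway = "synthetic",
                   map = map)
}
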
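# Shared fixtures, all generated in code.

# small dataset with arbitrary dosages (uniform over 0/1/2)
toy_dataset <- function(n = 20, p = 5, seed = 1, y = NULL, pop = "P1") {
  set.seed(seed)
  G <- matrix(sample(0:2, n * p, replace = TRUE), n, p,
              dimnames = list(NULL, sprintf("M%04d", seq_len(p))))
  if (is.null(y)) y <- stats::rnorm(n)
  gp_dataset(sprintf("R%03d", seq_len(n)), pop, G, y)
}

# additive trait with a single causal marker, high signal
one_qtl_dataset <- function(n = 120, p = 10, causal = 4, h2 = 0.9, seed = 1) {
  set.seed(seed)
  G <- matrix(sample(0:2, n * p, replace = TRUE), n, p,
              dimnames = list(NULL, sprintf("M%04d", seq_len(p))))
  g <- G[, causal] * 1.0
  sd_e <- sqrt(stats::var(g) * (1 - h2) / h2)
  gp_dataset(sprintf("R%03d", seq_len(n)), "P1", G,
             g + stats::rnorm(n, 0, sd_e))
}

# standard BC1S4 simulation used by the recovery tests: maize-like geometry
# (10 chromosomes x 150 cM), two additive QTL plus one epistatic pair.
# Causal markers are chosen >= 20 cM from their preceding neighbour so the
# loci stay identifiable under LD pruning (rather than visible only through
# an LD proxy).
sim_two_qtl <- function(n_ril = 200, p = 100, h2 = 0.7, seed = 1) {
  mp <- simulate_map(10, 150, p, seed = seed)
  tab <- mp$table
  gap_prev <- unlist(tapply(tab$position_cM, tab$chromosome,
                            function(x) c(Inf, diff(x))))
  pick <- function(chrom) {
    cols <- which(tab$chromosome == chrom & gap_prev >= 20)
    if (!length(cols)) cols <- which(tab$chromosome == chrom)
    cols[which.min(abs(tab$position_cM[cols] - 75))]
  }
  q1 <- pick(3); q2 <- pick(7)
  tr <- truth_architecture(c(q1, q2), c(1.0, -0.8),
                           epistatic_pairs = cbind(q1, q2),
                           epi_effects = 1.2, h2 = h2)
  sim <- simulate_ril_population(sim_config(n_ril, mp, seed = seed + 1), tr)
  list(sim = sim, map = mp, truth = tr,
       causal = tab$marker[c(q1, q2)])
}

write_toy_csv <- function(path, dup_id = FALSE, empty_cell = FALSE) {
  lines <- c("id,population,replicate,M0001,M0002,M0003,DTA",
             "R1,P1,0,0,1,2,70.5",
             sprintf("%s,P1,0,1,1,0,71.2", if (dup_id) "R1" else "R2"),
             sprintf("R3,P1,0,2,%s,1,69.8", if (empty_cell) "" else "0"),
             "R4,P1,0,0,2,2,72.0")
  writeLines(lines, path)
  path
}

n_records_public <- function(d) nrow(d$G)

toy_dataset_with_na <- function() {
  d <- toy_dataset(n = 10, p = 3, seed = 3)
  d$G[1, 2] <- NA
  d
}
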
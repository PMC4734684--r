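# Shared fixtures, all built in code.

AA20 <- amino_acids()

# independent copy of the five-way category partition, for oracle use
CAT5 <- c(R = "pos", H = "pos", K = "pos",
          D = "neg", E = "neg",
          S = "pol", T = "pol", N = "pol", Q = "pol",
          A = "hyd", I = "hyd", L = "hyd", M = "hyd", F = "hyd",
          W = "hyd", Y = "hyd", V = "hyd",
          C = "sp", G = "sp", P = "sp")

random_motifs <- function(n, terminal = "N", alphabet = AA20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  res <- matrix(sample(alphabet, 3L * n, replace = TRUE), ncol = 3L)
  motif_string(res, terminal)
}

# small simulated affinity set for pipeline tests
small_library <- function(n = 60L, terminal = "N", noise_sd = 0,
                          seed = 1L, truth_seed = 2L) {
  lib <- enumerate_sublibrary(terminal)
  set.seed(seed)
  lib <- lib[sort(sample.int(nrow(lib), n)), , drop = FALSE]
  truth <- ground_truth("linear-sparse", noise_sd = noise_sd,
                        seed = truth_seed)
  simulate_affinities(lib, truth, seed = seed)
}

# quick config for tests that exercise the CV machinery
fast_config <- function(seed = 1L, ...) {
  en_config(nfolds = 5L, nlambda = 20L, tol = 1e-2, seed = seed, ...)
}
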
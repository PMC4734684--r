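test_that("top_k orders by affinity with a lexicographic tie-break", {
  recs <- data.frame(
    motif_id = paste0("m", 1:5), terminal = "N",
    sequence = c("RRRsXXX", "AAAsXXX", "GGGsXXX", "EEEsXXX", "KKKsXXX"),
    affinity = c(5, 9, 3, 3, 3))
  expect_equal(top_k(recs, 5)$sequence, recs$sequence[order(-recs$affinity,
                                                            recs$sequence)])
  # three-way tie at the cut: the lexicographically smallest survives
  expect_equal(top_k(recs, 3)$sequence,
               c("AAAsXXX", "RRRsXXX", "EEEsXXX"))
  expect_error(top_k(recs, 0), "k > 0")
  expect_error(top_k(recs, 9))
})

test_that("position frequencies normalize per covered position", {
  pwm <- position_frequencies(rep("RAFsXXX", 4))
  expect_s3_class(pwm, "pep_pwm")
  expect_equal(pwm["P-3", "R"], 1)
  expect_equal(pwm["P-2", "A"], 1)
  expect_true(all(is.na(pwm["P+1", ])))  # absent terminal flagged, not 0
  covered <- c("P-3", "P-2", "P-1")
  expect_equal(unname(rowSums(pwm[covered, ])), rep(1, 3))
  # equal weights reproduce plain frequencies
  recs <- data.frame(sequence = c("RAFsXXX", "EAFsXXX"), affinity = c(2, 2))
  expect_equal(unclass(position_frequencies(recs, "affinity-weighted")),
               unclass(position_frequencies(recs$sequence)),
               ignore_attr = TRUE)
  expect_error(position_frequencies(character(0)), "no motifs")
})

test_that("uniform random motifs approach uniform position frequencies", {
  set.seed(17)
  n <- 8000
  pwm <- position_frequencies(random_motifs(n, "C"))
  se <- sqrt(0.05 * 0.95 / n)
  # bound on the max over 60 cells, hence wider than a per-cell band
  expect_lt(max(abs(pwm[c("P+1", "P+2", "P+3"), ] - 1 / 20)), 5 * se)
})

test_that("consensus and isoform-specific calls match set algebra", {
  set.seed(18)
  pool <- random_motifs(60, "N")
  lists <- lapply(1:7, function(i) sample(pool, 30))
  names(lists) <- c("beta", "epsilon", "eta", "gamma", "sigma", "tau",
                    "zeta")
  cons <- consensus_binders(lists)
  expect_setequal(cons, Reduce(intersect, lists))
  expect_true(all(vapply(lists, function(l) all(cons %in% l), logical(1))))
  spec <- isoform_specific(lists, "sigma")
  oracle <- setdiff(lists$sigma, unlist(lists[names(lists) != "sigma"]))
  expect_setequal(spec, oracle)
  for (other in setdiff(names(lists), "sigma")) {
    expect_length(intersect(spec, lists[[other]]), 0L)
  }
  # identical lists under distinct isoform names: full consensus, no
  # specificity
  same <- stats::setNames(lists[c(1, 1, 1)], c("iso1", "iso2", "iso3"))
  expect_setequal(consensus_binders(same), unique(lists[[1]]))
  expect_length(isoform_specific(same, "iso1"), 0L)
  expect_length(consensus_binders(c(lists, list(none = character(0)))), 0L)
  expect_error(isoform_specific(lists, "delta"), "unknown isoform")
})

test_that("similarity scoring applies the 3/1/0 rule per position", {
  self <- similarity_score("RAG", "RAG")
  expect_equal(self$total, 9L)
  # published worked examples: sigma-specific motifs vs reference binder
  # LFGpSLLR (N-side triple LFG, C-side triple LLR)
  n_scores <- vapply(c("RAG", "EAK", "RGG"), function(m) {
    similarity_score(m, "LFG")$total
  }, integer(1))
  expect_setequal(n_scores, c(1L, 3L, 4L))
  expect_equal(similarity_score("XXXsFGP", "LLR")$total, 1L)
  # symmetry on random pairs
  set.seed(19)
  for (i in 1:50) {
    a <- sample(AA20, 3, TRUE); b <- sample(AA20, 3, TRUE)
    sa <- similarity_score(a, b); sb <- similarity_score(b, a)
    expect_identical(sa$total, sb$total)
    expect_true(all(sa$per_position %in% c(0L, 1L, 3L)))
    expect_equal(sum(sa$per_position), sa$total)
  }
})

test_that("randomization p-values match the exact null distribution", {
  # exact enumeration oracle over the 20^3 residue triples
  exact_tail <- function(ref, cut) {
    per_pos <- lapply(1:3, function(j) {
      sc <- ifelse(AA20 == ref[j], 3L,
                   ifelse(CAT5[AA20] == CAT5[ref[j]], 1L, 0L))
      table(factor(sc, levels = 0:3)) / 20
    })
    tot <- outer(outer(0:3, 0:3, "+"), 0:3, "+")
    pr <- outer(outer(as.numeric(per_pos[[1]]),
                      as.numeric(per_pos[[2]])),
                as.numeric(per_pos[[3]]))
    sum(pr[tot >= cut])
  }
  ref <- c("L", "F", "G")
  p_hat <- randomization_pvalue(4, ref, n_iter = 100000, seed = 41)
  p_exact <- exact_tail(ref, 4)
  se <- sqrt(p_exact * (1 - p_exact) / 100000)
  expect_lt(abs(p_hat - p_exact), 3 * se)
  # trivial anchors
  expect_equal(randomization_pvalue(0, ref, n_iter = 50, seed = 1), 1)
  expect_equal(randomization_pvalue(10, ref, n_iter = 50, seed = 1), 0)
})

test_that("Monte-Carlo error halves when iterations quadruple", {
  ref <- c("L", "F", "G")
  est <- function(n_iter, seeds) {
    vapply(seeds, function(s) {
      randomization_pvalue(4, ref, n_iter = n_iter, seed = s)
    }, numeric(1))
  }
  sd_small <- sd(est(500, 1:40))
  sd_big <- sd(est(2000, 1:40))
  expect_lt(sd_big, sd_small / 1.5)
})

test_that("building-block null alphabets are oriented by terminal", {
  # P in the outermost slot only: N-terminal null puts p3 alphabet first
  p_n <- randomization_pvalue(9, c("P", "A", "A"), "blocks", "N",
                              n_iter = 2000, seed = 7)
  expect_gt(p_n, 0)
  expect_error(randomization_pvalue(1, c("L", "F", "G"),
                                    list("A", character(0), "C")),
               "empty null alphabet")
})
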
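test_that("pairwise_counts classifies substitutions and excludes gaps/Ns", {
  c0 <- pairwise_counts("ACGT", "ACGT")
  expect_equal(c(c0$L, c0$P1, c0$P2, c0$Q), c(4, 0, 0, 0))
  c1 <- pairwise_counts("ACGT", "GCGT")
  expect_equal(c(c1$L, c1$P1, c1$P2, c1$Q), c(4, 1, 0, 0))
  c2 <- pairwise_counts("ACG-", "ACGT")
  expect_equal(c(c2$L, c2$P1, c2$P2, c2$Q), c(3, 0, 0, 0))
  c3 <- pairwise_counts("ACNT", "AGTC")
  expect_equal(c(c3$L, c3$P1, c3$P2, c3$Q), c(3, 0, 1, 1))
  expect_error(pairwise_counts("ACG", "ACGT"), "length")
  expect_equal(sum(c1[, c("pi_A", "pi_C", "pi_G", "pi_T")]), 1,
               tolerance = 1e-12)
})

test_that("tn93_distance matches independent oracles", {
  expect_equal(tn93_distance(pairwise_counts("ACGTACGT", "ACGTACGT")), 0)
  # toy pair with uniform frequencies against the model-based oracle
  cts <- tibble::tibble(L = 100, P1 = 6, P2 = 4, Q = 2,
                        pi_A = 0.25, pi_C = 0.25, pi_G = 0.25, pi_T = 0.25)
  expect_equal(tn93_distance(cts),
               tn93_model_dist(0.06, 0.04, 0.02, rep(0.25, 4)),
               tolerance = 1e-8)
  # unequal frequencies
  cts2 <- tibble::tibble(L = 1000, P1 = 50, P2 = 30, Q = 40,
                         pi_A = 0.3, pi_C = 0.2, pi_G = 0.3, pi_T = 0.2)
  expect_equal(tn93_distance(cts2),
               tn93_model_dist(0.05, 0.03, 0.04, c(0.3, 0.2, 0.3, 0.2)),
               tolerance = 1e-8)
  # K2P limit: uniform frequencies and P1 = P2
  cts3 <- tibble::tibble(L = 200, P1 = 10, P2 = 10, Q = 8,
                         pi_A = 0.25, pi_C = 0.25, pi_G = 0.25, pi_T = 0.25)
  expect_equal(tn93_distance(cts3), k2p_dist(20 / 200, 8 / 200),
               tolerance = 1e-10)
  # saturation flagged, not clamped
  sat <- tibble::tibble(L = 10, P1 = 5, P2 = 3, Q = 2,
                        pi_A = 0.25, pi_C = 0.25, pi_G = 0.25, pi_T = 0.25)
  expect_warning(expect_true(is.na(tn93_distance(sat))), "saturated")
})

test_that("tn93 agrees with ape and is symmetric", {
  set.seed(3)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:3) {
    s1 <- sample(bases, 400, TRUE, prob = c(0.3, 0.2, 0.3, 0.2))
    s2 <- s1
    mut <- runif(400) < 0.1
    s2[mut] <- sample(bases, sum(mut), TRUE)
    a <- paste0(s1, collapse = ""); b <- paste0(s2, collapse = "")
    mine <- tn93_distance(pairwise_counts(a, b))
    expect_equal(mine, tn93_distance(pairwise_counts(b, a)))
    m <- rbind(s1, s2); rownames(m) <- c("x", "y")
    expect_equal(mine,
                 as.numeric(ape::dist.dna(ape::as.DNAbin(m), model = "TN93",
                                          pairwise.deletion = TRUE)),
                 tolerance = 1e-10)
  }
})

test_that("mean TN93 over JC replicates is close to the true distance", {
  set.seed(77)
  for (d in c(0.05, 0.1, 0.2)) {
    tr <- ape::read.tree(text = sprintf("(a:%f,b:%f);", d / 2, d / 2))
    est <- replicate(200, {
      a <- sim_sequences(tr, "JC", L_seq = 300)
      suppressWarnings(tn93_distance(pairwise_counts(a$sequence[1],
                                                     a$sequence[2])))
    })
    est <- est[!is.na(est)]
    se <- sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - d), 3 * se + 0.002)
  }
})

test_that("saturation_series rows, verdicts and plot", {
  two <- alignment(c("a", "b"), c("ACGTACGT", "ACGTACGA"))
  expect_equal(nrow(saturation_series(two)), 1)

  set.seed(5)
  shallow_tree <- sim_coalescent_tree(12, nu = 0.0125)  # depth ~ 0.025
  shallow <- sim_sequences(shallow_tree, "HKY", kappa = 4, L_seq = 800)
  ss1 <- saturation_series(shallow)
  expect_equal(attr(ss1, "verdict"), "not saturated")

  deep_tree <- sim_coalescent_tree(12, nu = 1.5)
  deep <- sim_sequences(deep_tree, "HKY", kappa = 6, L_seq = 800)
  ss2 <- saturation_series(deep)
  expect_equal(attr(ss2, "verdict"), "saturated")
  expect_lt(attr(ss2, "slope_upper"), 0.5 * attr(ss2, "slope_lower"))
  expect_s3_class(autoplot(ss2), "ggplot")

  expect_error(saturation_series(shallow, positions = "no_third"),
               "frame")
})

test_that("ry_recode hits third positions only and is idempotent", {
  expect_equal(ry_recode(alignment("x", "ATG"), frame = 1)$sequence, "ATR")
  a <- alignment(c("x", "y"), c("ATGACC", "ATAACT"))
  r1 <- ry_recode(a, frame = 1)
  expect_equal(r1$sequence, c("ATRACY", "ATRACY"))
  expect_equal(ry_recode(r1, frame = 1)$sequence, r1$sequence)
  # gap at third position preserved
  expect_equal(ry_recode(alignment("x", "AC-"), frame = 1)$sequence, "AC-")
  # frame 2: positions 1, 4 are third-codon
  expect_equal(ry_recode(alignment("x", "TAAT"), frame = 2)$sequence, "YAAY")
  expect_error(ry_recode(alignment("x", "ATG")), "frame")
})

test_that("base_composition_test matches the contingency-table oracle", {
  ident <- alignment(c("a", "b", "c"), c("ACGT", "ACGT", "ACGT"))
  bc0 <- base_composition_test(ident)
  expect_equal(bc0$statistic, 0)
  expect_equal(bc0$p_value, 1)

  bc <- base_composition_test(alignment(c("a", "b"), c("AAAA", "CCCC")))
  expect_equal(bc$statistic, 8)
  expect_equal(bc$df, 3)

  # oracle: chisq.test on a random non-degenerate count table
  set.seed(8)
  bases <- c("A", "C", "G", "T")
  seqs <- replicate(5, paste0(sample(bases, 120, TRUE,
                                     prob = runif(4) + 0.2), collapse = ""))
  aln <- alignment(paste0("t", 1:5), seqs)
  bc2 <- base_composition_test(aln)
  tab <- do.call(rbind, lapply(strsplit(seqs, ""), function(s)
    table(factor(s, bases))))
  or <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  expect_equal(bc2$statistic, unname(or$statistic), tolerance = 1e-10)
  expect_equal(bc2$df, unname(or$parameter))
  expect_equal(bc2$p_value, chisq_tail_quad(bc2$statistic, bc2$df),
               tolerance = 1e-8)

  # permutation invariance
  perm <- aln[c(3, 1, 5, 2, 4), ]
  expect_equal(base_composition_test(perm)$statistic, bc2$statistic)

  # df bookkeeping at the study scale: 122 taxa -> 363
  expect_equal((122 - 1) * 3, 363)
  expect_error(base_composition_test(alignment(c("a", "b"), c("NN--", "ACGT"))),
               "zero countable")
})

test_that("mito_translation_screen applies the vertebrate mitochondrial code", {
  expect_true(mito_translation_screen("ATGGCC", 1)$pass)
  bad <- mito_translation_screen("ATGTAAGCC", 1)
  expect_false(bad$pass)
  expect_equal(bad$stops$codon_index, 2L)
  expect_equal(bad$stops$codon, "TAA")
  # AGA is a stop under the vertebrate mitochondrial code
  expect_false(mito_translation_screen("AGA", 1)$pass)
  # frame shift rescues a stop
  expect_false(mito_translation_screen("TAGCTA", 1)$pass)
  expect_true(mito_translation_screen("TAGCTA", 2)$pass)
  expect_error(mito_translation_screen("AT", 1), "codon")
})
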
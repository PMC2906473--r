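test_that("interval_rate_null matches hand values and guards n < 2", {
  expect_equal(interval_rate_null(2, 1, 1), 2)
  expect_equal(interval_rate_null(5, 0.5, 1), 10)
  expect_equal(interval_rate_null(5, 0.5, 0), 0.5)
  expect_error(interval_rate_null(1, 1, 1), ">= 2")
})

test_that("single-interval likelihood contribution is analytic", {
  # ln b - b x with b = 1 * (2*1)^1 = 2, x = 0.5
  b <- interval_rate_null(2, 1, 1)
  expect_equal(log(b) - b * 0.5, log(2) - 1)
  expect_equal(log(2) - 1, -0.30685, tolerance = 1e-4)
})

test_that("fit_null closed-form lambda at fixed p is respected", {
  # schedule x = [1, 1], n = [2, 3], p = 1: lambda_hat = 2 / (2 + 6)
  sched <- tibble::tibble(event = 1:3, node = 4:6, age = c(2, 1, 0.2),
                          n_lineages = 2:4, waiting = c(1, 0.8, NA))
  x <- c(1, 1); f <- c(2, 6)
  lam <- length(x) / sum(f * x)
  expect_equal(lam, 0.25)
  # the fitted p-profiled optimum must dominate the p = 1 closed form
  fit <- fit_null(tibble::tibble(event = 1:3, node = 4:6, age = c(2, 1, 0),
                                 n_lineages = 2:4, waiting = c(1, 1, NA)))
  logl_p1 <- sum(log(lam * f) - lam * f * x)
  expect_gte(fit$logL, logl_p1 - 1e-9)
})

test_that("fit_null matches a dense grid-search oracle", {
  set.seed(21)
  n_iv <- 20
  x <- rexp(n_iv, 5)
  nl <- 2:(n_iv + 1)
  sched <- tibble::tibble(event = seq_len(n_iv + 1), node = 0,
                          age = c(rev(cumsum(rev(x))), 0),
                          n_lineages = c(nl, n_iv + 2),
                          waiting = c(x, NA))
  fit <- fit_null(sched)
  oracle <- oracle_grid_null(x, nl * (nl - 1))
  expect_lt(abs(fit$logL - oracle$logL), 1e-4)
  expect_error(fit_null(dplyr::mutate(sched, waiting = c(rep(0, n_iv), NA))),
               "degenerate")
})

test_that("classify_nodes applies the age rule and coalescent tie-break", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  cls <- classify_nodes(tr, -1.5)
  expect_equal(cls$class[order(cls$age, decreasing = TRUE)],
               c("diversification", "coalescent"))
  expect_true(all(classify_nodes(tr, -0.01)$class[-1] == "coalescent") ||
                all(classify_nodes(tr, -0.01)$class == "diversification"))
  # just younger than every node: everything diversification
  expect_true(all(classify_nodes(tr, -0.01)$class == "diversification"))
  # tie: node exactly at |T| goes coalescent
  expect_equal(classify_nodes(tr, -1)$class[classify_nodes(tr, -1)$age == 1],
               "coalescent")
  expect_error(classify_nodes(tr, -2.5), "strictly between")
})

test_that("extract_partition forms clusters and singletons correctly", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  p1 <- extract_partition(tr, -1.5)
  expect_equal(attr(p1, "K"), 2L)
  expect_equal(sort(p1$label[p1$kind == "cluster"]), c("A", "B"))
  expect_equal(p1$label[p1$kind == "singleton"], "C")
  expect_equal(dplyr::n_distinct(p1$entity[p1$label %in% c("A", "B")]), 1)

  p2 <- extract_partition(tr, -0.5)
  expect_equal(attr(p2, "K"), 3L)
  expect_true(all(p2$kind == "singleton"))
})

test_that("a mid-range threshold on a well-separated simulation recovers truth", {
  sim <- sim_gmyc_tree(sim_config(n_species = 10, m = 4, s = 20, nu = 0.005,
                                  seed = 12))
  # choose any threshold between the deepest genealogy and the shallowest stem
  stopifnot(max(sim$species$depth) < min(sim$species$parent_age))
  Tsep <- (max(sim$species$depth) + min(sim$species$parent_age)) / 2
  part <- extract_partition(sim$tree, -Tsep)
  expect_equal(attr(part, "K"), 10L)
  truth <- sim$partition$entity[match(part$label, sim$partition$label)]
  tab <- table(truth, part$entity)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
})

test_that("likelihood_ratio_test reproduces the published arithmetic", {
  lrt <- likelihood_ratio_test(700.133, 687.218, 3)
  expect_equal(lrt$statistic, 25.83, tolerance = 1e-12)
  expect_lt(lrt$p_value, 1e-4)
  expect_equal(likelihood_ratio_test(5, 5, 3)$statistic, 0)
  expect_equal(likelihood_ratio_test(5, 5, 3)$p_value, 1)
  expect_error(likelihood_ratio_test(680, 687.218, 3), "failed")
})

test_that("chi-square upper tail matches the quadrature oracle", {
  for (case in list(c(25.83, 3), c(2.5, 3), c(10, 1), c(0.3, 5))) {
    expect_equal(stats::pchisq(case[1], case[2], lower.tail = FALSE),
                 chisq_tail_quad(case[1], case[2]), tolerance = 1e-8)
  }
})

test_that("confidence_set keeps rows within delta of the maximum", {
  prof <- tibble::tibble(threshold = c(-0.3, -0.2, -0.1),
                         logL = c(-10, -9, -12), K = c(5L, 6L, 4L))
  cs <- confidence_set(prof, 2)
  expect_equal(c(cs$K_min, cs$K_max), c(5L, 6L))
  expect_equal(c(cs$T_min, cs$T_max), c(-0.3, -0.2))
  one <- confidence_set(prof[2, ], 2)
  expect_equal(c(one$K_min, one$K_max), c(6L, 6L))
})

test_that("fit_gmyc recovers a well-separated simulated partition", {
  sim <- sim_gmyc_tree(sim_config(n_species = 10, m = 4, s = 20, nu = 0.005,
                                  seed = 12))
  fit <- fit_gmyc(sim$tree)
  expect_equal(fit$K, 10L)
  truth <- sim$partition$entity[match(fit$partition$label, sim$partition$label)]
  tab <- table(truth, fit$partition$entity)
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  expect_lt(fit$lrt$p_value, 0.05)
  # threshold separates the two regimes
  expect_gt(abs(fit$threshold), max(sim$species$depth))
  expect_lt(abs(fit$threshold), min(sim$species$parent_age))
})

test_that("fit_gmyc guards degenerate inputs", {
  expect_error(fit_gmyc(parse_newick("((A:1,B:1):1,C:2);")),
               "too few candidate thresholds")
  expect_error(fit_gmyc(parse_newick("(((A:1,B:2):1,C:3):1,D:4);")),
               "not ultrametric")
})

test_that("per-threshold ML log-likelihoods match the dense grid oracle", {
  for (tr in fixture_trees()) {
    fit <- fit_gmyc(tr, n_starts = 2)
    prof <- fit$profile
    root_age <- max(node_ages(tr))
    for (i in seq_len(nrow(prof))) {
      Tpos <- abs(prof$threshold[i])
      if (Tpos >= root_age - 1e-12) next  # root row equals the null by design
      g <- oracle_grid_gmyc(oracle_interval_data(tr, Tpos))
      expect_lt(abs(g$logL - prof$logL[i]), 1e-3)
    }
  }
})

test_that("GMYC nests the null and df is 3 on every fixture", {
  for (tr in fixture_trees()) {
    fit <- fit_gmyc(tr)
    expect_gte(fit$logL, fit$null$logL - 1e-6)
    expect_equal(fit$df, 3L)
    expect_equal(fit$lrt$df, 3)
  }
  sim <- sim_gmyc_tree(sim_config(n_species = 8, m = 3, seed = 2))
  fit <- fit_gmyc(sim$tree)
  expect_gte(fit$logL, fit$null$logL - 1e-6)
})

test_that("partitions are disjoint, exhaustive and monophyletic", {
  sim <- sim_gmyc_tree(sim_config(n_species = 8, m = 3, seed = 9))
  fit <- fit_gmyc(sim$tree)
  part <- fit$partition
  expect_setequal(part$label, sim$tree$tip.label)
  expect_equal(anyDuplicated(part$label), 0)
  for (e in unique(part$entity)) {
    tips <- part$label[part$entity == e]
    if (length(tips) >= 2) {
      expect_true(ape::is.monophyletic(sim$tree, tips))
    }
  }
})

test_that("entity count is non-increasing as the threshold moves rootward", {
  sim <- sim_gmyc_tree(sim_config(n_species = 8, m = 3, seed = 4))
  ages <- sort(unique(ape::branching.times(sim$tree)), decreasing = TRUE)
  grid <- seq(min(ages) * 0.5, max(ages) * 0.999, length.out = 40)
  ks <- vapply(grid, function(Tpos)
    attr(extract_partition(sim$tree, -Tpos), "K"), integer(1))
  expect_true(all(diff(ks) <= 0))
})

test_that("per-cluster and pooled coalescent forms coincide at p2 = 1", {
  tr <- fixture_trees()$mixed6
  td <- gmycbar:::gmyc_tree_data(tr)
  for (Tpos in c(0.35, 0.65, 1.2)) {
    st <- gmycbar:::threshold_stats(td, Tpos)
    for (par in list(c(0.5, 0.7, 2), c(2, -1, 0.3))) {
      a <- gmycbar:::gmyc_loglik_at(st, par[1], par[2], par[3], 1,
                                    form = "per_cluster")
      b <- gmycbar:::gmyc_loglik_at(st, par[1], par[2], par[3], 1,
                                    form = "pooled")
      expect_equal(a, b, tolerance = 1e-12)
    }
  }
  # both forms fit end to end
  f1 <- fit_gmyc(tr, coalescent_form = "per_cluster")
  f2 <- fit_gmyc(tr, coalescent_form = "pooled")
  expect_gte(f1$logL, f1$null$logL - 1e-6)
  expect_gte(f2$logL, f2$null$logL - 1e-6)
})

test_that("tidy and glance expose the profile and the summary", {
  sim <- sim_gmyc_tree(sim_config(n_species = 6, m = 3, seed = 8))
  fit <- fit_gmyc(sim$tree)
  prof <- tidy(fit)
  expect_true(all(c("threshold", "logL", "K") %in% names(prof)))
  expect_equal(max(prof$logL), fit$logL)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$K, fit$K)
  expect_equal(gl$statistic, fit$lrt$statistic)
  expect_gte(gl$K_max, gl$K_min)
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(autoplot(fit, type = "profile"), "ggplot")
})
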
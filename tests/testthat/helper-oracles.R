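# Independent oracles used across the suite. These re-derive quantities by
# brute force or from first principles, sharing no code path with the
# package internals they check.

# ---- trees -----------------------------------------------------------------

fixture_trees <- function() {
  list(
    caterpillar4 = parse_newick("(((A:1,B:1):1,C:2):1,D:3);"),
    balanced4 = parse_newick("((A:1,B:1):1.5,(C:1.2,D:1.2):1.3);"),
    mixed6 = parse_newick(
      "(((A:0.2,B:0.2):1.8,(C:0.5,D:0.5):1.5):1,(E:0.8,F:0.8):2.2);"),
    caterpillar8 = parse_newick(paste0(
      "(((((((A:0.1,B:0.1):0.3,C:0.4):0.35,D:0.75):0.45,E:1.2):0.5,",
      "F:1.7):0.55,G:2.25):0.75,H:3);"))
  )
}

# ---- mixed-likelihood oracle ----------------------------------------------

# Interval composition derived independently: ages from ape, intervals
# between consecutive distinct internal-node ages, lineages counted by
# strict age spans at interval midpoints, clusters found by walking each
# edge's ancestor chain. Requires distinct node ages (fixtures comply).
oracle_interval_data <- function(tree, Tpos) {
  n <- ape::Ntip(tree)
  bt <- ape::branching.times(tree)
  age <- numeric(n + tree$Nnode)
  age[as.integer(names(bt))] <- bt
  ages_sorted <- sort(unique(round(bt, 12)), decreasing = TRUE)
  stopifnot(length(ages_sorted) == tree$Nnode)  # oracle needs distinct ages
  p_age <- age[tree$edge[, 1]]
  c_age <- age[tree$edge[, 2]]
  # crossing ancestor per node by path walking
  crossing_child <- function(v) {
    path <- v
    while (v != n + 1) {
      v <- tree$edge[tree$edge[, 2] == v, 1]
      path <- c(path, v)
    }
    cross <- which(age[path] <= Tpos & c(age[path[-1]], Inf) > Tpos)
    if (length(cross)) path[cross[1]] else NA_integer_
  }
  m <- length(ages_sorted) - 1          # inter-event intervals
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    hi <- ages_sorted[i]; lo <- ages_sorted[i + 1]
    t <- (hi + lo) / 2
    span <- p_age > t & c_age < t
    sp <- span & p_age > Tpos
    ns <- sum(sp)
    cl_edges <- which(span & !sp)
    cl_id <- vapply(cl_edges, function(e) crossing_child(tree$edge[e, 2]),
                    integer(1))
    cnt <- as.numeric(table(cl_id))
    pairs <- cnt * (cnt - 1)
    rows[[i]] <- list(x = hi - lo, ns = ns, pairs = pairs[pairs > 0])
  }
  rows
}

oracle_gmyc_logl <- function(rows, l1, p1, l2, p2, form = "per_cluster") {
  tot <- 0
  for (r in rows) {
    D <- if (r$ns > 0) r$ns^p1 else 0
    S <- if (length(r$pairs)) {
      if (form == "per_cluster") sum(r$pairs^p2) else sum(r$pairs)^p2
    } else 0
    B <- l1 * D + l2 * S
    if (B <= 0) return(-Inf)
    tot <- tot + log(B) - B * r$x
  }
  tot
}

# Dense grid search with successive refinement (pure grid; no gradients).
# Hierarchical dense grid: an outer refined grid over the exponent pair,
# and for each exponent point an inner refined grid over the two log rate
# scales (on which the log-likelihood is concave, so zooming cannot be
# trapped). Pure grid search throughout.
oracle_grid_gmyc <- function(rows, form = "per_cluster",
                             outer_rounds = 6, inner_rounds = 5,
                             n_outer = 17, n_inner = 15) {
  m <- length(rows)
  x <- vapply(rows, `[[`, numeric(1), "x")
  ns <- vapply(rows, `[[`, numeric(1), "ns")
  inner_max <- function(p1, p2) {
    D <- ifelse(ns > 0, ns^p1, 0)
    S <- vapply(rows, function(r) {
      if (!length(r$pairs)) 0 else
        if (form == "per_cluster") sum(r$pairs^p2) else sum(r$pairs)^p2
    }, numeric(1))
    rl1 <- c(-12, 12); rl2 <- c(-12, 12)
    best_v <- -Inf; best_l <- c(0, 0)
    for (r in seq_len(inner_rounds)) {
      g1 <- exp(seq(rl1[1], rl1[2], length.out = n_inner))
      g2 <- exp(seq(rl2[1], rl2[2], length.out = n_inner))
      val <- matrix(0, n_inner, n_inner)
      for (i in seq_len(m)) {
        B <- outer(g1 * D[i], g2 * S[i], "+")
        val <- val + log(B) - B * x[i]
      }
      val[!is.finite(val)] <- -Inf
      k <- arrayInd(which.max(val), dim(val))
      if (val[k] > best_v) {
        best_v <- val[k]
        best_l <- c(log(g1[k[1]]), log(g2[k[2]]))
      }
      w1 <- diff(rl1) / (n_inner - 1) * 1.5
      w2 <- diff(rl2) / (n_inner - 1) * 1.5
      rl1 <- best_l[1] + c(-w1, w1); rl2 <- best_l[2] + c(-w2, w2)
    }
    best_v
  }
  rp1 <- c(-5, 5); rp2 <- c(-5, 5)
  best_val <- -Inf; best_p <- c(1, 1)
  for (r in seq_len(outer_rounds)) {
    gp1 <- seq(rp1[1], rp1[2], length.out = n_outer)
    gp2 <- seq(rp2[1], rp2[2], length.out = n_outer)
    for (a in gp1) for (b in gp2) {
      v <- inner_max(a, b)
      if (v > best_val) { best_val <- v; best_p <- c(a, b) }
    }
    w1 <- diff(rp1) / (n_outer - 1) * 2
    w2 <- diff(rp2) / (n_outer - 1) * 2
    rp1 <- pmin(pmax(best_p[1] + c(-w1, w1), -5), 5)
    rp2 <- pmin(pmax(best_p[2] + c(-w2, w2), -5), 5)
  }
  list(logL = best_val, par = best_p)
}

# Null-model oracle: dense two-stage grid over (log lambda, p);
# 400 x 400 per stage, second stage zoomed on the first's maximum.
oracle_grid_null <- function(x, f, n_grid = 400) {
  E <- length(x)
  rng_l <- c(-8, 8); rng_p <- c(-5, 5)
  best <- c(0, 1); best_val <- -Inf
  for (stage in 1:2) {
    ls <- seq(rng_l[1], rng_l[2], length.out = n_grid)
    ps <- seq(rng_p[1], rng_p[2], length.out = n_grid)
    for (p in ps) {
      fp <- f^p
      vals <- E * ls + p * sum(log(f)) - exp(ls) * sum(fp * x)
      k <- which.max(vals)
      if (vals[k] > best_val) { best_val <- vals[k]; best <- c(ls[k], p) }
    }
    wl <- diff(rng_l) / n_grid * 4; wp <- diff(rng_p) / n_grid * 4
    rng_l <- best[1] + c(-wl, wl); rng_p <- best[2] + c(-wp, wp)
  }
  list(logL = best_val, lambda = exp(best[1]), p = best[2])
}

# ---- distributional oracles ------------------------------------------------

# Upper-tail chi-square probability by quadrature over the hand-written
# density.
chisq_tail_quad <- function(stat, df) {
  dens <- function(t) exp((df / 2 - 1) * log(t) - t / 2 -
                            (df / 2) * log(2) - lgamma(df / 2))
  stats::integrate(dens, stat, Inf, rel.tol = 1e-12)$value
}

# Kimura two-parameter distance, closed form.
k2p_dist <- function(P, Q) {
  -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
}

# Independent reimplementation of the closed-form TN93 estimator, organized
# as per-class expected-substitution terms rather than the package's
# log-argument form.
tn93_closed_indep <- function(L, P1n, P2n, Qn, piA, piC, piG, piT) {
  P1 <- P1n / L; P2 <- P2n / L; Q <- Qn / L
  gR <- piA + piG; gY <- piC + piT
  c1 <- 2 * piA * piG / gR
  c2 <- 2 * piC * piT / gY
  c3 <- 2 * gR * gY
  w1 <- 1 - P1 / c1 - Q / (2 * gR)
  w2 <- 1 - P2 / c2 - Q / (2 * gY)
  w3 <- 1 - Q / c3
  # transversion weight: total minus the parts already absorbed by the
  # transition terms
  c3b <- c3 - 2 * (piA * piG * gY / gR + piC * piT * gR / gY)
  -(c1 * log(w1) + c2 * log(w2) + c3b * log(w3))
}

# TN93 distance solved independently from the substitution model itself:
# find the rate-matrix scaling under which the model's expected transition/
# transversion proportions match the observed ones (via matrix exponential),
# then read off the expected number of substitutions per site.
tn93_model_dist <- function(P1, P2, Q, pi) {
  names(pi) <- c("A", "C", "G", "T")
  rate_matrix <- function(a1, a2, b) {
    R <- matrix(b, 4, 4, dimnames = list(names(pi), names(pi)))
    R["A", "G"] <- a1; R["G", "A"] <- a1
    R["C", "T"] <- a2; R["T", "C"] <- a2
    Qm <- R * rep(pi, each = 4)
    diag(Qm) <- 0
    diag(Qm) <- -rowSums(Qm)
    Qm
  }
  moments <- function(par) {
    Qm <- rate_matrix(exp(par[1]), exp(par[2]), exp(par[3]))
    P <- as.matrix(Matrix::expm(Qm))
    J <- pi * P                       # joint distribution of (from, to)
    c(P1 = J["A", "G"] + J["G", "A"],
      P2 = J["C", "T"] + J["T", "C"],
      Q = sum(J) - sum(diag(J)) - (J["A", "G"] + J["G", "A"] +
                                     J["C", "T"] + J["T", "C"]))
  }
  obj <- function(par) sum((moments(par) - c(P1, P2, Q))^2)
  fit <- stats::optim(c(0, 0, 0), obj, control = list(reltol = 1e-16,
                                                      maxit = 5000))
  fit <- stats::optim(fit$par, obj, control = list(reltol = 1e-16,
                                                   maxit = 5000))
  Qm <- rate_matrix(exp(fit$par[1]), exp(fit$par[2]), exp(fit$par[3]))
  -sum(pi * diag(Qm))
}

# ---- barcode brute force ---------------------------------------------------

# Re-verify every diagnostic rule directly against the raw alignment, and
# confirm no pure diagnostic was missed, by full enumeration.
brute_force_diagnostics <- function(aln, partition) {
  mat <- do.call(rbind, strsplit(aln$sequence, ""))
  ent <- partition$entity[match(aln$label, partition$label)]
  bases <- c("A", "C", "G", "T")
  hits <- list()
  for (e in sort(unique(ent))) {
    for (col in seq_len(ncol(mat))) {
      states <- unique(mat[ent == e, col])
      if (length(states) == 1 && states %in% bases &&
          !any(mat[ent != e, col] == states)) {
        hits[[length(hits) + 1]] <- data.frame(entity = e, column = col,
                                               state = states)
      }
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(entity = integer(), column = integer(), state = character())
}
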
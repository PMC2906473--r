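#' Coalescent-family interval branching rate
#'
#' Rate of the power-coalescent branching family, `b = lambda * (n(n-1))^p`.
#' At `p = 1` this is the standard coalescent proportionality to the number
#' of lineage pairs.
#'
#' @param n Lineage count (>= 2); vectorized.
#' @param lambda Rate scale (> 0).
#' @param p Exponent.
#' @return Numeric rate(s).
#' @examples
#' interval_rate_null(2, 1, 1)   # 2
#' interval_rate_null(5, 0.5, 1) # 10
#' @export
interval_rate_null <- function(n, lambda, p) {
  if (any(n < 2)) stop("lineage count must be >= 2", call. = FALSE)
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  lambda * (n * (n - 1))^p
}

# Internal: profile fit of the one-component family b_i = lambda * f_i^p.
# `x`, `f`: event intervals (one branching event ends each); `x0`, `f0`:
# optional censored intervals carrying survival only. For fixed p the
# maximizing lambda is (number of events) / sum(f^p x); the remaining 1-D
# profile in p is maximized numerically.
fit_power_rate <- function(x, f, x0 = numeric(), f0 = numeric(),
                           p_bounds = c(-5, 5)) {
  if (sum(x) + sum(x0) <= 0) stop("degenerate schedule: all waiting times are zero",
                                  call. = FALSE)
  E <- length(x)
  lf <- sum(log(f))
  prof <- function(p) {
    W <- sum(f^p * x) + if (length(x0)) sum(f0^p * x0) else 0
    E * log(E / W) + p * lf - E
  }
  # coarse grid then local refinement: the profile can be gently multimodal
  grid <- seq(p_bounds[1], p_bounds[2], length.out = 41)
  vals <- vapply(grid, prof, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(prof, c(lo, hi), maximum = TRUE, tol = 1e-10)
  p_hat <- opt$maximum
  if (vals[i] > opt$objective) p_hat <- grid[i]
  W <- sum(f^p_hat * x) + if (length(x0)) sum(f0^p_hat * x0) else 0
  list(lambda = E / W, p = p_hat, logL = prof(p_hat))
}

#' Fit the null single-coalescent branching model
#'
#' Under the null the whole sample derives from a single population: every
#' internode interval has branching rate `lambda * (n_i (n_i - 1))^p`. The
#' log-likelihood `sum_i [log b_i - b_i x_i]` is maximized over
#' `lambda > 0` and `p` in `p_bounds`.
#'
#' @param schedule A branching schedule from [branching_schedule()].
#' @param p_bounds Box for the exponent.
#' @param include_terminal Include the youngest-node-to-present interval as
#'   a censored survival factor (no event). Default `FALSE`.
#' @return An object of class `null_fit`: list with `lambda`, `p`, `logL`,
#'   `n_intervals`.
#' @examples
#' tr <- parse_newick("(((A:1,B:1):1,C:2):1,D:3);")
#' fit_null(branching_schedule(tr))
#' @export
fit_null <- function(schedule, p_bounds = c(-5, 5), include_terminal = FALSE) {
  iv <- schedule[!is.na(schedule$waiting), ]
  if (nrow(iv) < 2) stop("need >= 2 observed intervals", call. = FALSE)
  x <- iv$waiting
  f <- iv$n_lineages * (iv$n_lineages - 1)
  x0 <- numeric(); f0 <- numeric()
  if (include_terminal) {
    last <- schedule[nrow(schedule), ]
    n_tips <- last$n_lineages + 1L
    x0 <- last$age
    f0 <- n_tips * (n_tips - 1)
  }
  fit <- fit_power_rate(x, f, x0, f0, p_bounds)
  structure(list(lambda = fit$lambda, p = fit$p, logL = fit$logL,
                 n_intervals = nrow(iv), include_terminal = include_terminal),
            class = "null_fit")
}

#' @export
print.null_fit <- function(x, ...) {
  cat(sprintf("null coalescent fit: lambda = %.6g, p = %.4f, logL = %.4f (%d intervals)\n",
              x$lambda, x$p, x$logL, x$n_intervals))
  invisible(x)
}

#' Classify nodes relative to a threshold age
#'
#' Nodes older than the threshold magnitude are species-diversification
#' events; nodes at or younger than it are coalescent events (a node exactly
#' at the threshold goes to the coalescent class).
#'
#' @param tree An ultrametric `phylo` object.
#' @param threshold Threshold age; negative time-before-present as reported
#'   (`-0.07` style) or its positive magnitude.
#' @return A tibble `(node, age, class)` over internal nodes.
#' @export
classify_nodes <- function(tree, threshold) {
  Tpos <- abs(threshold)
  ages <- node_ages(tree)
  root_age <- max(ages)
  if (Tpos <= 0 || Tpos >= root_age) {
    stop("threshold must lie strictly between 0 and the root age", call. = FALSE)
  }
  n <- ape::Ntip(tree)
  internal <- (n + 1):(n + tree$Nnode)
  tibble::tibble(
    node = internal,
    age = ages[internal],
    class = ifelse(ages[internal] > Tpos, "diversification", "coalescent")
  )
}

#' Extract the putative-species partition at a threshold
#'
#' Each branch crossing the threshold age defines one entity containing all
#' tips below it; entities with a single tip are singletons, others clusters.
#'
#' @inheritParams classify_nodes
#' @return A tibble `(label, entity, kind)` with attribute `K` (entity
#'   count); entity ids are assigned in tree (cladewise) order.
#' @examples
#' extract_partition(parse_newick("((A:1,B:1):1,C:2);"), -1.5)
#' @export
extract_partition <- function(tree, threshold) {
  Tpos <- abs(threshold)
  ages <- node_ages(tree)
  root_age <- max(ages)
  if (Tpos <= 0 || Tpos >= root_age) {
    stop("threshold must lie strictly between 0 and the root age", call. = FALSE)
  }
  partition_at(tree, Tpos, ages)
}

# Internal: partition without the strict-interior check (the root-age
# boundary, where the model collapses to the null, maps every tip to one
# entity).
partition_at <- function(tree, Tpos, ages = node_ages(tree)) {
  n <- ape::Ntip(tree)
  if (Tpos >= max(ages)) {
    out <- tibble::tibble(label = tree$tip.label, entity = 1L,
                          kind = "cluster")
    attr(out, "K") <- 1L
    return(out)
  }
  tree_cw <- ape::reorder.phylo(tree, "cladewise")
  edge <- tree_cw$edge
  cl <- integer(n + tree_cw$Nnode)    # entity id per node; 0 = above threshold
  next_id <- 0L
  for (e in seq_len(nrow(edge))) {
    u <- edge[e, 1]; v <- edge[e, 2]
    if (ages[u] > Tpos && ages[v] <= Tpos) {
      next_id <- next_id + 1L
      cl[v] <- next_id
    } else if (ages[u] <= Tpos) {
      cl[v] <- cl[u]
    }
  }
  ent <- cl[seq_len(n)]
  sizes <- table(ent)
  out <- tibble::tibble(
    label = tree$tip.label,
    entity = ent,
    kind = ifelse(as.integer(sizes[as.character(ent)]) >= 2,
                  "cluster", "singleton")
  )
  attr(out, "K") <- next_id
  out
}

#' Likelihood ratio test between the GMYC and null models
#'
#' @param logL_gmyc,logL_null Maximized log-likelihoods of the nested pair.
#' @param df Difference in free parameters (3 for the single-threshold
#'   model: lambda1, p1, lambda2, p2, T versus lambda, p).
#' @return A one-row tibble `(statistic, df, p_value)` with
#'   `statistic = 2 (logL_gmyc - logL_null)` and the upper-tail chi-square
#'   probability.
#' @examples
#' likelihood_ratio_test(700.133, 687.218, 3)
#' @export
likelihood_ratio_test <- function(logL_gmyc, logL_null, df = 3) {
  if (df < 1) stop("df must be >= 1", call. = FALSE)
  if (logL_gmyc < logL_null - 1e-9) {
    stop("logL_gmyc < logL_null: the alternative optimization failed",
         call. = FALSE)
  }
  stat <- max(0, 2 * (logL_gmyc - logL_null))
  tibble::tibble(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Confidence set over the threshold profile
#'
#' Retains every candidate threshold whose log-likelihood falls within
#' `delta` log-likelihood units of the maximum and reports the ranges of
#' entity count and threshold over the retained rows.
#'
#' @param profile A tibble with columns `threshold`, `logL`, `K`.
#' @param delta Log-likelihood radius (default 2, the conventional
#'   2-log-likelihood support limit).
#' @return A one-row tibble `(K_min, K_max, T_min, T_max, n_retained)`.
#' @export
confidence_set <- function(profile, delta = 2) {
  stopifnot(nrow(profile) > 0, all(is.finite(profile$logL)))
  keep <- profile[profile$logL >= max(profile$logL) - delta, ]
  tibble::tibble(
    K_min = min(keep$K), K_max = max(keep$K),
    T_min = min(keep$threshold), T_max = max(keep$threshold),
    n_retained = nrow(keep)
  )
}

# ---- interval bookkeeping for the mixed likelihood -------------------------

# Internal: per-tree structures reused across candidate thresholds.
# Intervals are indexed 1..k-1 between consecutive events (event i+1 ends
# interval i) plus a terminal interval k (youngest node to present, no
# event). spans[i, e] says whether edge e is extant during interval i.
gmyc_tree_data <- function(tree) {
  n <- ape::Ntip(tree)
  ages <- node_ages(tree)
  sched <- branching_schedule(tree)
  tree_cw <- ape::reorder.phylo(tree, "cladewise")
  edge <- tree_cw$edge
  k <- nrow(sched)                     # number of events (n - 1)
  p_rank <- match(edge[, 1], sched$node)
  c_rank <- match(edge[, 2], sched$node)
  c_rank[is.na(c_rank)] <- k + 1L      # tips persist to the present
  m <- k                               # intervals incl. terminal
  spans <- matrix(FALSE, m, nrow(edge))
  for (e in seq_len(nrow(edge))) {
    lo <- p_rank[e]; hi <- min(c_rank[e] - 1L, m)
    if (lo <= hi) spans[lo:hi, e] <- TRUE
  }
  x <- c(sched$waiting[-k], sched$age[k])
  list(n = n, ages = ages, sched = sched, edge = edge,
       p_age = ages[edge[, 1]], c_age = ages[edge[, 2]],
       spans = spans, x = x, n_event_intervals = k - 1L)
}

# Internal: interval composition for one threshold magnitude.
# A lineage is species-level unless it is a proper descendant of a
# threshold-crossing branch; crossing branches themselves are species-level
# stems. Returns per-interval species-lineage counts and flattened
# per-cluster pair counts.
threshold_stats <- function(td, Tpos) {
  edge <- td$edge
  cl <- integer(td$n + max(edge))      # cluster id per node
  for (e in seq_len(nrow(edge))) {
    u <- edge[e, 1]; v <- edge[e, 2]
    if (td$p_age[e] > Tpos && td$c_age[e] <= Tpos) {
      cl[v] <- v
    } else if (td$p_age[e] <= Tpos) {
      cl[v] <- cl[u]
    }
  }
  edge_cl <- ifelse(td$p_age <= Tpos, cl[edge[, 1]], 0L)
  is_sp <- edge_cl == 0L
  m <- nrow(td$spans)
  ns <- as.integer(td$spans %*% is_sp)
  pair_int <- integer(0); pair_val <- numeric(0)
  pooled <- numeric(m)
  if (any(!is_sp)) {
    f <- factor(edge_cl[!is_sp])
    ind <- outer(edge_cl[!is_sp], as.integer(levels(f)), "==") * 1
    counts <- td$spans[, !is_sp, drop = FALSE] %*% ind
    pairs <- counts * (counts - 1)
    nz <- which(pairs > 0, arr.ind = TRUE)
    if (nrow(nz)) {
      ord <- order(nz[, 1])
      pair_int <- nz[ord, 1]
      pair_val <- pairs[nz][ord]
      pooled <- rowSums(pairs)
    }
  }
  K <- sum(td$p_age > Tpos & td$c_age <= Tpos)
  list(ns = ns, pair_int = pair_int, pair_val = pair_val, pooled = pooled,
       K = K, x = td$x, n_event = td$n_event_intervals)
}

# Internal: mixed log-likelihood for one threshold.
# B_i = lambda1 * ns_i^p1 + lambda2 * S_i(p2); the per-interval factor is
# the total-rate form B_i exp(-B_i x_i), the same structure as the null
# model (which is recovered exactly when the threshold sits at the root and
# the whole sample is one cluster).
gmyc_interval_terms <- function(st, p1, p2, form) {
  m <- length(st$ns)
  D <- ifelse(st$ns > 0, st$ns^p1, 0)
  if (form == "per_cluster") {
    S <- numeric(m)
    if (length(st$pair_val)) {
      agg <- rowsum(st$pair_val^p2, st$pair_int)
      S[as.integer(rownames(agg))] <- agg[, 1]
    }
  } else {
    S <- ifelse(st$pooled > 0, st$pooled^p2, 0)
  }
  list(D = D, S = S)
}

gmyc_loglik_at <- function(st, lambda1, p1, lambda2, p2,
                           form = "per_cluster", include_terminal = FALSE) {
  tm <- gmyc_interval_terms(st, p1, p2, form)
  me <- st$n_event
  idx <- if (include_terminal) seq_along(st$x) else seq_len(me)
  B <- lambda1 * tm$D + lambda2 * tm$S
  if (any(B[seq_len(me)] <= 0)) return(-Inf)
  sum(log(B[seq_len(me)])) - sum(B[idx] * st$x[idx])
}

# Internal: concave inner maximization over (lambda1, lambda2) for fixed
# exponents, by safeguarded Newton on the 2x2 system.
inner_lambda_max <- function(D, S, x, me, include_terminal) {
  idx <- if (include_terminal) seq_along(x) else seq_len(me)
  De <- D[seq_len(me)]; Se <- S[seq_len(me)]
  A1 <- sum(D[idx] * x[idx]); A2 <- sum(S[idx] * x[idx])
  has1 <- any(De > 0); has2 <- any(Se > 0)
  obj <- function(l1, l2) {
    B <- l1 * De + l2 * Se
    if (any(B <= 0)) return(-Inf)
    sum(log(B)) - l1 * A1 - l2 * A2
  }
  # degenerate axes: a component absent from every event interval only
  # penalizes, so its rate goes to the boundary 0
  if (!has2) {
    l1 <- if (A1 > 0) me / A1 else 1
    return(list(lambda1 = l1, lambda2 = 0, logL = obj(l1, 0)))
  }
  if (!has1) {
    l2 <- if (A2 > 0) me / A2 else 1
    return(list(lambda1 = 0, lambda2 = l2, logL = obj(0, l2)))
  }
  l <- c(me / (2 * max(A1, 1e-12)), me / (2 * max(A2, 1e-12)))
  f <- obj(l[1], l[2])
  for (it in 1:40) {
    B <- l[1] * De + l[2] * Se
    g <- c(sum(De / B) - A1, sum(Se / B) - A2)
    H11 <- -sum((De / B)^2); H22 <- -sum((Se / B)^2); H12 <- -sum(De * Se / B^2)
    det <- H11 * H22 - H12^2
    if (!is.finite(det) || abs(det) < 1e-300) break
    step <- c(H22 * g[1] - H12 * g[2], H11 * g[2] - H12 * g[1]) / -det
    t <- 1
    repeat {
      cand <- l + t * step
      if (all(cand > 0)) {
        fc <- obj(cand[1], cand[2])
        if (fc >= f - 1e-12) { l <- cand; f <- fc; break }
      }
      t <- t / 2
      if (t < 1e-10) break
    }
    if (sqrt(sum((t * step)^2)) < 1e-10 * (1 + sqrt(sum(l^2)))) break
  }
  list(lambda1 = l[1], lambda2 = l[2], logL = f)
}

# Internal: maximize the mixed likelihood at one threshold over all four
# parameters: Nelder-Mead over the exponents with the concave lambda
# problem profiled out at each step.
fit_threshold <- function(st, form, include_terminal, p_bounds,
                          p_starts = list(c(1, 1))) {
  clamp <- function(p) pmin(pmax(p, p_bounds[1]), p_bounds[2])
  eval_p <- function(p) {
    p <- clamp(p)
    tm <- gmyc_interval_terms(st, p[1], p[2], form)
    inner_lambda_max(tm$D, tm$S, st$x, st$n_event, include_terminal)
  }
  neg <- function(p) -eval_p(p)$logL
  best <- NULL
  for (p0 in p_starts) {
    opt <- stats::optim(clamp(p0), neg, method = "Nelder-Mead",
                        control = list(reltol = 1e-9, maxit = 300))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  p_hat <- clamp(best$par)
  inner <- eval_p(p_hat)
  list(lambda1 = inner$lambda1, p1 = p_hat[1],
       lambda2 = inner$lambda2, p2 = p_hat[2], logL = inner$logL)
}

#' Fit the single-threshold general mixed Yule coalescent model
#'
#' Profiles a threshold age over candidate positions (midpoints between
#' consecutive distinct node ages, a candidate inside the youngest
#' internode-to-present interval, and the root-age boundary at which the
#' model collapses to the null single-coalescent fit). At each candidate the
#' mixed interval likelihood is maximized over the diversification pair
#' (lambda1, p1) and the coalescent pair (lambda2, p2); the maximum
#' likelihood threshold yields the putative-species partition, the LRT
#' against the null, and 2-log-likelihood confidence sets on the entity
#' count and the threshold.
#'
#' @param tree An ultrametric `phylo` object with >= 4 tips.
#' @param coalescent_form `"per_cluster"` applies the coalescent exponent
#'   inside the per-cluster sum, `lambda2 * sum_j (n_j (n_j - 1))^p2`
#'   (default); `"pooled"` applies it outside,
#'   `lambda2 * (sum_j n_j (n_j - 1))^p2`. The two coincide at `p2 = 1`.
#' @param include_terminal Carry the youngest-node-to-present interval as a
#'   censored survival factor. Default `FALSE` (no event is observed there).
#' @param p_bounds Box constraint for both exponents.
#' @param delta Log-likelihood radius of the confidence sets.
#' @param rel_tol Ultrametricity tolerance forwarded to
#'   [check_ultrametric()].
#' @param n_starts Extra exponent starts per candidate beyond the warm start
#'   carried along the threshold sweep.
#' @return An object of class `gmyc_fit`; see [glance.gmyc_fit()] and
#'   [tidy.gmyc_fit()] for tabular views.
#' @examples
#' sim <- sim_gmyc_tree(sim_config(n_species = 6, m = 3, seed = 1))
#' fit <- fit_gmyc(sim$tree)
#' glance(fit)
#' @export
fit_gmyc <- function(tree,
                     coalescent_form = c("per_cluster", "pooled"),
                     include_terminal = FALSE,
                     p_bounds = c(-5, 5),
                     delta = 2,
                     rel_tol = 1e-6,
                     n_starts = 1) {
  coalescent_form <- match.arg(coalescent_form)
  if (ape::Ntip(tree) < 4) {
    stop("too few candidate thresholds: need >= 4 tips", call. = FALSE)
  }
  chk <- check_ultrametric(tree, rel_tol)
  if (!chk$pass) {
    stop("tree is not ultrametric (see check_ultrametric); max deviation ",
         signif(chk$max_deviation, 3), call. = FALSE)
  }
  sched <- branching_schedule(tree)
  null <- fit_null(sched, p_bounds, include_terminal = include_terminal)
  td <- gmyc_tree_data(tree)
  root_age <- max(td$ages)

  d <- sort(unique(sched$age), decreasing = TRUE)
  # collapse float-level age ties so candidate midpoints are genuine
  d <- d[c(TRUE, diff(d) < -1e-9 * root_age)]
  cands <- c((d[-length(d)] + d[-1]) / 2, d[length(d)] / 2)
  if (length(cands) < 2) {
    stop("too few candidate thresholds", call. = FALSE)
  }

  rows <- vector("list", length(cands))
  warm <- c(1, 1)
  for (j in seq_along(cands)) {
    st <- threshold_stats(td, cands[j])
    starts <- list(warm, c(null$p, null$p), c(1, 1))[seq_len(max(1, n_starts + 1))]
    ft <- fit_threshold(st, coalescent_form, include_terminal, p_bounds, starts)
    warm <- c(ft$p1, ft$p2)
    rows[[j]] <- tibble::tibble(
      threshold = -cands[j], logL = ft$logL, K = st$K,
      lambda1 = ft$lambda1, p1 = ft$p1, lambda2 = ft$lambda2, p2 = ft$p2
    )
  }
  profile <- dplyr::bind_rows(rows)
  root_row <- tibble::tibble(
    threshold = -root_age, logL = null$logL, K = 1L,
    lambda1 = NA_real_, p1 = NA_real_, lambda2 = null$lambda, p2 = null$p
  )
  profile <- dplyr::arrange(dplyr::bind_rows(profile, root_row),
                            .data$threshold)

  best <- which.max(profile$logL)
  T_hat <- profile$threshold[best]
  logL_gmyc <- profile$logL[best]
  partition <- partition_at(tree, abs(T_hat), td$ages)
  lrt <- likelihood_ratio_test(logL_gmyc, null$logL, df = 3)
  conf <- confidence_set(profile, delta)

  structure(list(
    tree = tree,
    threshold = T_hat,
    params = tibble::tibble(lambda1 = profile$lambda1[best],
                            p1 = profile$p1[best],
                            lambda2 = profile$lambda2[best],
                            p2 = profile$p2[best],
                            threshold = T_hat),
    logL = logL_gmyc,
    null = null,
    lrt = lrt,
    df = 3L,
    partition = partition,
    K = attr(partition, "K"),
    confidence = conf,
    profile = profile,
    options = list(coalescent_form = coalescent_form,
                   include_terminal = include_terminal,
                   p_bounds = p_bounds, delta = delta)
  ), class = "gmyc_fit")
}

#' @export
print.gmyc_fit <- function(x, ...) {
  k <- x$partition
  n_singleton <- sum(k$kind == "singleton" & !duplicated(k$entity))
  cat("single-threshold GMYC fit\n")
  cat(sprintf("  logL (GMYC) = %.4f, logL (null) = %.4f\n", x$logL, x$null$logL))
  cat(sprintf("  LRT: 2dL = %.4f, df = %d, p = %.4g\n",
              x$lrt$statistic, x$lrt$df, x$lrt$p_value))
  cat(sprintf("  ML threshold T = %.6g\n", x$threshold))
  cat(sprintf("  entities: %d (%d singletons); K confidence set [%d, %d]\n",
              x$K, n_singleton, x$confidence$K_min, x$confidence$K_max))
  cat(sprintf("  threshold confidence range [%.6g, %.6g]\n",
              x$confidence$T_min, x$confidence$T_max))
  invisible(x)
}
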
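#' Simulation configuration
#'
#' Collects the parameters of the tree/alignment/clone simulators. The
#' defaults describe the study conditions the delimitation pipeline is
#' validated under: a moderate radiation (15 species under a pure-birth
#' process of rate 1 per lineage per unit time), 4 sampled individuals per
#' species, shallow within-species genealogies (expected pairwise
#' coalescence time `nu = 0.005` in tree-time units) kept at least a factor
#' `s = 10` shallower than each species' stem, and ancient-DNA clone sets
#' with deamination probability 0.02 and background miscall rate 0.001 per
#' site per clone.
#'
#' @param n_species Number of species tips in the Yule tree.
#' @param lambda_spec Speciation rate per lineage per unit time.
#' @param m Samples per species; scalar or length-`n_species` vector.
#' @param nu Expected pairwise within-species coalescence time.
#' @param s Separation factor (>= 1): a species' genealogy is redrawn until
#'   its depth is below its stem-parent age divided by `s`.
#' @param model Substitution model for [sim_sequences()].
#' @param kappa Transition/transversion rate parameter (HKY).
#' @param pi Base frequencies (A, C, G, T), summing to 1.
#' @param L_seq Alignment length in sites.
#' @param rate Rate scale multiplying branch lengths before sequence
#'   evolution (substitutions per site per unit tree time).
#' @param delta Per-site per-clone cytosine-deamination probability.
#' @param epsilon Per-site per-clone background misincorporation
#'   probability.
#' @param n_pcr Number of independent PCR batches of clones.
#' @param clones_per_pcr Clones sequenced per batch.
#' @param seed Random seed; recorded in every simulator output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_species = 15, lambda_spec = 1, m = 4, nu = 0.005,
                       s = 10, model = c("JC", "HKY"), kappa = 2,
                       pi = c(0.25, 0.25, 0.25, 0.25), L_seq = 500,
                       rate = 1, delta = 0.02, epsilon = 0.001,
                       n_pcr = 2, clones_per_pcr = 8, seed = NULL) {
  model <- match.arg(model)
  stopifnot(n_species >= 2, lambda_spec > 0, all(m >= 1), nu > 0, s >= 1,
            kappa > 0, length(pi) == 4, all(pi >= 0),
            abs(sum(pi) - 1) < 1e-8, L_seq >= 1, rate > 0,
            delta >= 0, delta <= 1, epsilon >= 0, epsilon <= 1,
            n_pcr >= 1, clones_per_pcr >= 1)
  structure(list(n_species = n_species, lambda_spec = lambda_spec, m = m,
                 nu = nu, s = s, model = model, kappa = kappa, pi = pi,
                 L_seq = L_seq, rate = rate, delta = delta,
                 epsilon = epsilon, n_pcr = n_pcr,
                 clones_per_pcr = clones_per_pcr, seed = seed),
            class = "sim_config")
}

#' Node ages of a simulated pure-birth (Yule) tree
#'
#' Draws the speciation ages only: starting from the root split (2
#' lineages), the waiting time while `k` lineages exist is exponential with
#' rate `k * lambda`, and after the `n`-th lineage appears one further
#' exponential waiting time separates the last split from the present.
#'
#' @param n_species Number of tips (>= 2).
#' @param lambda Speciation rate (> 0).
#' @return Numeric vector of `n_species - 1` node ages (time before
#'   present), decreasing; the first element is the root age.
#' @export
sim_yule_ages <- function(n_species, lambda) {
  stopifnot(n_species >= 2, lambda > 0)
  w <- stats::rexp(n_species - 1, rate = (2:n_species) * lambda)
  depth <- sum(w)
  depth - c(0, cumsum(w[-length(w)]))
}

#' Coalescence ages of a Kingman genealogy
#'
#' While `k` lineages remain, the waiting time to the next coalescence is
#' exponential with rate `k (k - 1) / (2 nu)`, so the expected coalescence
#' time of a sampled pair is exactly `nu`.
#'
#' @param m Number of tips (>= 1).
#' @param nu Expected pairwise coalescence time (> 0).
#' @return Numeric vector of `m - 1` coalescence ages (time before
#'   present), increasing; the last element is the genealogy depth. Length
#'   0 for `m = 1`.
#' @export
sim_coalescent_ages <- function(m, nu) {
  stopifnot(m >= 1, nu > 0)
  if (m == 1) return(numeric(0))
  k <- m:2
  cumsum(stats::rexp(m - 1, rate = k * (k - 1) / (2 * nu)))
}

# Internal: assemble a labelled binary tree from coalescence ages (from
# present, increasing) by merging uniformly random pairs; returns a Newick
# fragment (no trailing ";") and its depth. Both the Yule and the Kingman
# simulators reduce to this: their labelled shape is the uniform
# random-join distribution.
merge_fragment <- function(labels, ages) {
  frags <- labels
  born <- rep(0, length(labels))
  for (a in ages) {
    pick <- sample.int(length(frags), 2)
    f <- sprintf("(%s:%.12g,%s:%.12g)",
                 frags[pick[1]], a - born[pick[1]],
                 frags[pick[2]], a - born[pick[2]])
    frags <- c(frags[-pick], f)
    born <- c(born[-pick], a)
  }
  list(newick = frags[1], depth = if (length(ages)) ages[length(ages)] else 0)
}

#' Simulate a pure-birth species tree
#'
#' @inheritParams sim_yule_ages
#' @param seed Optional seed for reproducibility.
#' @param labels Tip labels (default `sp01`, `sp02`, ...).
#' @return An ultrametric `phylo` object with `n_species` tips.
#' @export
sim_yule_tree <- function(n_species, lambda = 1, seed = NULL, labels = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels)) {
    labels <- sprintf("sp%02d", seq_len(n_species))
  }
  stopifnot(length(labels) == n_species)
  ages <- sort(sim_yule_ages(n_species, lambda))
  fr <- merge_fragment(labels, ages)
  ape::read.tree(text = paste0(fr$newick, ";"))
}

#' Simulate a single-population Kingman genealogy
#'
#' @inheritParams sim_coalescent_ages
#' @param seed Optional seed.
#' @param labels Tip labels (default `t1`, `t2`, ...).
#' @return An ultrametric `phylo` object (`m >= 2`).
#' @export
sim_coalescent_tree <- function(m, nu = 1, seed = NULL, labels = NULL) {
  stopifnot(m >= 2)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(labels)) labels <- paste0("t", seq_len(m))
  stopifnot(length(labels) == m)
  fr <- merge_fragment(labels, sim_coalescent_ages(m, nu))
  ape::read.tree(text = paste0(fr$newick, ";"))
}

#' Simulate a species tree with embedded within-species genealogies
#'
#' Draws a pure-birth species tree, then for each species an independent
#' Kingman genealogy over its samples, redrawn until its depth is smaller
#' than the species' stem-parent age divided by the separation factor `s`
#' (rejection keeps the genealogy exactly Kingman conditioned on the
#' bound), and grafts it in place of the species tip so that all sampled
#' individuals sit at the present.
#'
#' @param config A [sim_config()]; `n_species`, `lambda_spec`, `m`, `nu`,
#'   `s` and `seed` are used.
#' @param max_attempts Rejection budget per species before giving up.
#' @return A list of class `gmyc_sim`: `tree` (ultrametric `phylo` over all
#'   samples), `partition` (truth tibble `label`, `entity`, `kind`),
#'   `species` (per-species tibble with stem-parent age, genealogy depth and
#'   rejection count), and the echoed `config`.
#' @export
sim_gmyc_tree <- function(config = sim_config(), max_attempts = 10000) {
  if (!is.null(config$seed)) set.seed(config$seed)
  ns <- config$n_species
  m <- rep_len(config$m, ns)
  sp_labels <- sprintf("sp%02d", seq_len(ns))
  sp_tree <- {
    ages <- sort(sim_yule_ages(ns, config$lambda_spec))
    fr <- merge_fragment(sp_labels, ages)
    ape::read.tree(text = paste0(fr$newick, ";"))
  }
  ages_sp <- node_ages(sp_tree)
  tip_no <- match(sp_labels, sp_tree$tip.label)
  parent_age <- vapply(tip_no, function(i) {
    e <- which(sp_tree$edge[, 2] == i)
    ages_sp[sp_tree$edge[e, 1]]
  }, numeric(1))

  frags <- character(ns); depths <- numeric(ns); rejections <- integer(ns)
  for (i in seq_len(ns)) {
    labs <- if (m[i] == 1) sp_labels[i] else
      sprintf("%s_%d", sp_labels[i], seq_len(m[i]))
    if (m[i] == 1) {
      frags[i] <- labs; depths[i] <- 0
      next
    }
    bound <- parent_age[i] / config$s
    ok <- FALSE
    for (att in seq_len(max_attempts)) {
      ca <- sim_coalescent_ages(m[i], config$nu)
      if (ca[length(ca)] < bound) {
        rejections[i] <- att - 1L
        fr <- merge_fragment(labs, ca)
        frags[i] <- fr$newick; depths[i] <- fr$depth
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("rejection rate > 99% over ", max_attempts, " attempts for species ",
           sp_labels[i], ": use a smaller nu or separation factor s",
           call. = FALSE)
    }
  }

  # graft: replace each species tip label in the species-tree Newick by its
  # genealogy fragment, shortening the stem by the genealogy depth
  nwk <- write_newick(sp_tree)
  for (i in seq_len(ns)) {
    tip_edge <- which(sp_tree$edge[, 2] == tip_no[i])
    stem <- sp_tree$edge.length[tip_edge] - depths[i]
    nwk <- sub(paste0(sp_labels[i], ":[0-9.eE+-]+"),
               sprintf("%s:%.12g", frags[i], stem), nwk)
  }
  tree <- ape::read.tree(text = nwk)

  partition <- tibble::tibble(
    label = tree$tip.label,
    entity = match(sub("_.*$", "", tree$tip.label), sp_labels),
    kind = ifelse(m[match(sub("_.*$", "", tree$tip.label), sp_labels)] >= 2,
                  "cluster", "singleton")
  )
  structure(list(
    tree = tree,
    partition = partition,
    species = tibble::tibble(species = sp_labels, m = m,
                             parent_age = parent_age, depth = depths,
                             rejections = rejections),
    config = config
  ), class = "gmyc_sim")
}

#' Evolve an alignment along a tree
#'
#' Continuous-time Markov simulation (JC or HKY) down the tree, root state
#' drawn from the stationary frequencies. Branch lengths are interpreted as
#' expected substitutions per site after multiplication by `rate`.
#'
#' @param tree A `phylo` object.
#' @param model `"JC"` or `"HKY"`.
#' @param kappa Transition/transversion rate parameter (HKY; `kappa = 1`
#'   with uniform frequencies reduces to JC).
#' @param pi Base frequencies (A, C, G, T).
#' @param L_seq Number of sites.
#' @param rate Rate scale applied to branch lengths.
#' @param seed Optional seed.
#' @return An alignment tibble `(label, sequence)`.
#' @export
sim_sequences <- function(tree, model = c("JC", "HKY"), kappa = 2,
                          pi = c(0.25, 0.25, 0.25, 0.25), L_seq = 500,
                          rate = 1, seed = NULL) {
  model <- match.arg(model)
  stopifnot(length(pi) == 4, all(pi >= 0), abs(sum(pi) - 1) < 1e-8, kappa > 0)
  if (!is.null(seed)) set.seed(seed)
  tr <- tree
  tr$edge.length <- tr$edge.length * rate
  if (model == "JC") {
    Q <- rep(1, 6); bf <- rep(0.25, 4)
  } else {
    # exchangeabilities in phangorn order (AC, AG, AT, CG, CT, GT)
    Q <- c(1, kappa, 1, 1, kappa, 1); bf <- pi
  }
  dat <- phangorn::simSeq(tr, l = L_seq, Q = Q, bf = bf, type = "DNA")
  mat <- toupper(as.character(dat))
  tibble::tibble(label = rownames(mat),
                 sequence = unname(apply(mat, 1, paste0, collapse = "")))
}

#' Simulate deamination-damaged clone sets
#'
#' Each clone copies the template and is damaged independently per site:
#' with probability `delta` a C becomes T and a G becomes A (deamination as
#' seen on either strand); afterwards, with probability `epsilon`, any site
#' is replaced by a uniformly random different base.
#'
#' @param template Template sequence (A/C/G/T string).
#' @param n_pcr Number of independent PCR batches.
#' @param clones_per_pcr Clones per batch.
#' @param delta Per-site deamination probability.
#' @param epsilon Per-site misincorporation probability.
#' @param seed Optional seed.
#' @return A tibble `(pcr, clone, sequence)` with attribute `template`.
#' @export
sim_clones <- function(template, n_pcr = 2, clones_per_pcr = 8,
                       delta = 0.02, epsilon = 0.001, seed = NULL) {
  stopifnot(delta >= 0, delta <= 1, epsilon >= 0, epsilon <= 1,
            n_pcr >= 1, clones_per_pcr >= 1)
  if (!is.null(seed)) set.seed(seed)
  tchars <- strsplit(toupper(template), "")[[1]]
  if (!all(tchars %in% c("A", "C", "G", "T"))) {
    stop("template must contain only A/C/G/T", call. = FALSE)
  }
  L <- length(tchars)
  bases <- c("A", "C", "G", "T")
  rows <- list()
  idx <- 0
  for (b in seq_len(n_pcr)) {
    for (cl in seq_len(clones_per_pcr)) {
      s <- tchars
      deam <- stats::runif(L) < delta
      s[deam & tchars == "C"] <- "T"
      s[deam & tchars == "G"] <- "A"
      err <- which(stats::runif(L) < epsilon)
      for (j in err) s[j] <- sample(setdiff(bases, s[j]), 1)
      idx <- idx + 1
      rows[[idx]] <- tibble::tibble(pcr = b, clone = cl,
                                    sequence = paste0(s, collapse = ""))
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "template") <- paste0(tchars, collapse = "")
  out
}
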
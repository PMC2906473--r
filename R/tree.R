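#' Parse a Newick string into a rooted ultrametric-ready tree
#'
#' Reads a Newick description, checks that branch lengths are present and
#' non-negative, and resolves any polytomies into arbitrary bifurcations
#' joined by zero-length branches (with a warning). Node ages are measured
#' back from the present (tips at 0, root oldest); use [check_ultrametric()]
#' to validate clock-likeness.
#'
#' @param text A single Newick string (terminated by `;`), with branch
#'   lengths on all edges.
#' @return A rooted, binary `phylo` object.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' node_ages(tr)
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- trimws(text)
  # locate unbalanced parentheses before handing over to the parser so the
  # error can name a position
  chars <- strsplit(text, "")[[1]]
  depth <- 0
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1
    if (chars[i] == ")") {
      depth <- depth - 1
      if (depth < 0) {
        stop("malformed Newick: unmatched ')' at position ", i, call. = FALSE)
      }
    }
  }
  if (depth > 0) {
    stop("malformed Newick: ", depth, " unclosed '(' by position ",
         nchar(text), call. = FALSE)
  }
  if (!grepl(";\\s*$", text)) {
    stop("malformed Newick: missing terminal ';' at position ", nchar(text),
         call. = FALSE)
  }
  tree <- withCallingHandlers(
    ape::read.tree(text = text),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("malformed Newick: parser failed on the supplied string", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("missing branch lengths: every edge must carry a length", call. = FALSE)
  }
  if (anyNA(tree$edge.length)) {
    bad <- which(is.na(tree$edge.length))[1]
    stop("missing branch length on edge ", bad, call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch length encountered", call. = FALSE)
  }
  if (!ape::is.binary(tree)) {
    warning("polytomies resolved into zero-length bifurcations", call. = FALSE)
    tree <- ape::multi2di(tree, random = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (!ape::is.rooted(tree)) {
    stop("tree must be rooted", call. = FALSE)
  }
  tree
}

#' Read a Newick tree from a file
#'
#' @param path Path to a Newick file (first tree used).
#' @return A `phylo` object, validated as in [parse_newick()].
#' @export
read_newick <- function(path) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Write a tree to Newick
#'
#' @param tree A `phylo` object.
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Node ages of a rooted tree
#'
#' Ages are time before present: the deepest tip defines the present (age 0)
#' and the root carries the maximum age.
#'
#' @param tree A rooted `phylo` object with branch lengths.
#' @return Numeric vector of ages indexed by ape node number
#'   (tips `1..n`, then internal nodes).
#' @export
node_ages <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  # the present is anchored at the typical (median) tip depth, so that on a
  # near-clock tree the deviant tips are the ones flagged, not the majority
  root_age <- stats::median(depth[seq_len(ape::Ntip(tree))])
  root_age - depth
}

#' Validate that a tree is ultrametric
#'
#' Checks that every tip age is 0 within a relative tolerance of the root
#' age. Reports; never mutates.
#'
#' @param tree A rooted `phylo` object.
#' @param rel_tol Allowed tip-age deviation as a fraction of the root age.
#' @return An object of class `ultrametric_check`: a list with `pass`,
#'   `max_deviation`, `root_age`, `rel_tol` and an `offenders` tibble
#'   (tip, age) for tips beyond tolerance.
#' @export
check_ultrametric <- function(tree, rel_tol = 1e-6) {
  ages <- node_ages(tree)
  n <- ape::Ntip(tree)
  tip_ages <- ages[seq_len(n)]
  root_age <- max(ages)
  dev <- abs(tip_ages)
  bad <- dev > rel_tol * root_age
  out <- list(
    pass = !any(bad),
    max_deviation = if (n) max(dev) else 0,
    root_age = root_age,
    rel_tol = rel_tol,
    offenders = tibble::tibble(tip = tree$tip.label[bad], deviation = dev[bad])
  )
  class(out) <- "ultrametric_check"
  out
}

#' @export
print.ultrametric_check <- function(x, ...) {
  cat(if (x$pass) "ultrametric: PASS" else "ultrametric: FAIL",
      sprintf(" (max tip-age deviation %.3g of root age %.6g, tol %g)\n",
              x$max_deviation, x$root_age, x$rel_tol))
  if (nrow(x$offenders)) print(x$offenders)
  invisible(x)
}

#' Force near-ultrametric trees onto the clock
#'
#' Adjusts terminal branch lengths only, setting each tip age exactly to 0.
#' Refuses trees whose worst tip deviates by more than `max_rel_dev` of the
#' root age: such trees are genuinely additive, not round-off victims.
#'
#' @param tree A rooted `phylo` object.
#' @param max_rel_dev Largest correctable relative deviation.
#' @return The adjusted `phylo` object.
#' @export
force_ultrametric <- function(tree, max_rel_dev = 1e-3) {
  ages <- node_ages(tree)
  n <- ape::Ntip(tree)
  root_age <- max(ages)
  dev <- abs(ages[seq_len(n)])
  if (max(dev) > max_rel_dev * root_age) {
    stop("tree deviates from ultrametricity by ", signif(max(dev), 3),
         " (> ", max_rel_dev, " of root age); refusing to adjust", call. = FALSE)
  }
  tip_edges <- match(seq_len(n), tree$edge[, 2])
  tree$edge.length[tip_edges] <- tree$edge.length[tip_edges] + ages[seq_len(n)]
  tree
}

#' Rescale a tree to a target root depth
#'
#' Multiplies every branch length by `target_depth / root age`, the
#' convention under which the time separating the root from the present is
#' assigned to 1 before model fitting so that reported thresholds are
#' comparable across trees.
#'
#' @param tree A rooted `phylo` object with root age > 0.
#' @param target_depth Desired root age (default 1).
#' @return The rescaled `phylo` object.
#' @export
rescale_root <- function(tree, target_depth = 1) {
  root_age <- max(node_ages(tree))
  if (root_age <= 0) {
    stop("root age is 0: degenerate star at the present cannot be rescaled",
         call. = FALSE)
  }
  tree$edge.length <- tree$edge.length * (target_depth / root_age)
  tree
}

# Internal: internal-node event order (age descending, ties broken by
# preorder position so a parent always precedes its zero-length child).
event_order <- function(tree) {
  n <- ape::Ntip(tree)
  ages <- node_ages(tree)
  internal <- (n + 1):(n + tree$Nnode)
  reord <- ape::reorder.phylo(tree, "cladewise")
  pre <- unique(c(n + 1L, reord$edge[, 2]))
  pre_rank <- match(internal, pre)
  internal[order(-ages[internal], pre_rank)]
}

#' Branching schedule of an ultrametric tree
#'
#' The sufficient statistic for the branching-process likelihoods: node
#' events ordered from the root toward the present, the waiting time to the
#' next event, and the number of lineages present during that wait.
#'
#' @param tree An ultrametric `phylo` object with at least 3 tips.
#' @return A tibble with one row per internal node (oldest first):
#'   `event` (rank), `node` (ape node id), `age`, `n_lineages` (count during
#'   the interval that starts at this event) and `waiting` (interval length;
#'   `NA` for the youngest event, whose interval runs to the present).
#' @examples
#' branching_schedule(parse_newick("((A:1,B:1):1,C:2);"))
#' @export
branching_schedule <- function(tree) {
  n <- ape::Ntip(tree)
  if (n < 3) stop("branching schedule needs >= 3 tips", call. = FALSE)
  ages <- node_ages(tree)
  ord <- event_order(tree)
  a <- ages[ord]
  k <- length(ord)
  tibble::tibble(
    event = seq_len(k),
    node = ord,
    age = a,
    n_lineages = seq_len(k) + 1L,
    waiting = c(a[-k] - a[-1], NA_real_)
  )
}

#' Lineage-through-time series
#'
#' Step function of the number of lineages against age, starting at
#' (root age, 2) and ending with all tips at the age of the youngest node.
#'
#' @param tree An ultrametric `phylo` object.
#' @return A tibble `(age, n_lineages)`, ages descending; simultaneous
#'   events are collapsed into a single step.
#' @export
ltt_series <- function(tree) {
  sched <- branching_schedule(tree)
  dplyr::summarise(dplyr::group_by(sched, .data$age),
                   n_lineages = max(.data$n_lineages), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$age))
}

#' Plot a lineage-through-time series
#'
#' @param tree An ultrametric `phylo` object.
#' @param threshold Optional threshold age (negative, time before present)
#'   drawn as a vertical line.
#' @return A ggplot object: lineage count (log scale) against time before
#'   present (negative axis, present at 0).
#' @export
plot_ltt <- function(tree, threshold = NULL) {
  ltt <- ltt_series(tree)
  dat <- dplyr::mutate(ltt, time = -.data$age)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$n_lineages)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time before present", y = "lineages") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = -abs(threshold),
                                 linetype = "dashed", colour = "red")
  }
  p
}
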
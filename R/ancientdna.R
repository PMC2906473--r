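#' Consensus from cloned PCR products
#'
#' Per site, each PCR batch votes with the majority state of its clones
#' (within-batch ties abstain); a base is called only when the same
#' majority state is supported by at least two independent batches,
#' otherwise the site is N. This PCR-stratified rule operationalizes the
#' ancient-DNA requirement that a call be replicated across independent
#' amplifications.
#'
#' @param clones A tibble `(pcr, clone, sequence)` of equal-length clone
#'   sequences, as produced by [sim_clones()] or read from per-batch FASTA.
#' @param min_pcr Minimum number of independent PCR batches required.
#' @return A list of class `clone_consensus`: `consensus` (string), and
#'   `support`, a tibble with one row per site giving each batch's
#'   majority, the called state and an agreement flag.
#' @export
clone_consensus <- function(clones, min_pcr = 2) {
  batches <- sort(unique(clones$pcr))
  if (length(batches) < min_pcr) {
    stop("authentication requires >= ", min_pcr,
         " independent PCR batches (got ", length(batches), ")", call. = FALSE)
  }
  L <- unique(nchar(clones$sequence))
  if (length(L) != 1) stop("clone sequences differ in length", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  mats <- lapply(batches, function(b)
    do.call(rbind, strsplit(toupper(clones$sequence[clones$pcr == b]), "")))
  # per-batch per-site majority (ties -> NA)
  maj <- vapply(mats, function(m) {
    apply(m, 2, function(col) {
      cnt <- table(factor(col, bases))
      top <- which(cnt == max(cnt) & cnt > 0)
      if (length(top) == 1) bases[top] else NA_character_
    })
  }, character(L))
  called <- apply(maj, 1, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return("N")
    cnt <- table(v)
    top <- names(cnt)[cnt >= 2]
    if (length(top) == 1) top else "N"
  })
  support <- tibble::tibble(site = seq_len(L), called = called,
                            n_batches_agree = apply(maj, 1, function(v) {
                              v <- v[!is.na(v)]
                              if (!length(v)) 0L else max(table(v))
                            }))
  for (b in seq_along(batches)) {
    support[[paste0("pcr", batches[b])]] <- maj[, b]
  }
  structure(list(consensus = paste0(called, collapse = ""),
                 support = support, n_pcr = length(batches)),
            class = "clone_consensus")
}

#' @export
print.clone_consensus <- function(x, ...) {
  cat(sprintf("clone consensus over %d PCR batches: %d sites, %d called N\n",
              x$n_pcr, nchar(x$consensus),
              sum(strsplit(x$consensus, "")[[1]] == "N")))
  invisible(x)
}

#' Damage profile of clones against their consensus
#'
#' Tallies every clone-versus-consensus mismatch at called (non-N) sites
#' into the 12 directed substitution classes and reports the type-2
#' fraction, (C>T + G>A) / total: the signature of post-mortem cytosine
#' deamination observed on either strand.
#'
#' @param clones A tibble `(pcr, clone, sequence)`.
#' @param consensus Consensus string (a [clone_consensus()] object is also
#'   accepted).
#' @return A list of class `damage_report`: `total`, `classes` tibble
#'   `(from, to, count)`, `type2_fraction` (`NA` with `undefined = TRUE`
#'   when there are no mismatches).
#' @examples
#' cl <- tibble::tibble(pcr = c(1, 1, 2, 2), clone = c(1, 2, 1, 2),
#'                      sequence = c("ACGT", "ATGT", "ACGT", "ACGT"))
#' damage_report(cl, "ACGT")
#' @export
damage_report <- function(clones, consensus) {
  if (inherits(consensus, "clone_consensus")) consensus <- consensus$consensus
  cons <- strsplit(toupper(consensus), "")[[1]]
  if (any(nchar(clones$sequence) != length(cons))) {
    stop("clone and consensus lengths differ", call. = FALSE)
  }
  bases <- c("A", "C", "G", "T")
  classes <- expand.grid(from = bases, to = bases, stringsAsFactors = FALSE)
  classes <- classes[classes$from != classes$to, ]
  counts <- stats::setNames(numeric(nrow(classes)),
                            paste0(classes$from, ">", classes$to))
  called <- cons %in% bases
  for (s in clones$sequence) {
    cc <- strsplit(toupper(s), "")[[1]]
    mm <- called & cc %in% bases & cc != cons
    if (any(mm)) {
      key <- paste0(cons[mm], ">", cc[mm])
      tab <- table(key)
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
  }
  total <- sum(counts)
  type2 <- counts["C>T"] + counts["G>A"]
  structure(list(
    total = total,
    classes = tibble::tibble(from = classes$from, to = classes$to,
                             count = as.numeric(counts)),
    type2_fraction = if (total > 0) unname(type2 / total) else NA_real_,
    undefined = total == 0
  ), class = "damage_report")
}

#' @export
print.damage_report <- function(x, ...) {
  if (x$undefined) {
    cat("damage report: no mismatches (type-2 fraction undefined)\n")
  } else {
    cat(sprintf("damage report: %d mismatches, type-2 (C>T + G>A) fraction %.3f\n",
                as.integer(x$total), x$type2_fraction))
  }
  invisible(x)
}

#' Ancient-DNA authentication checklist
#'
#' Boolean per criterion: PCR blanks negative, at least two independent
#' PCR amplifications, a deamination-biased damage pattern (type-2 fraction
#' at least 0.5 whenever four or more mismatches were observed; with fewer
#' mismatches the criterion cannot be refuted and passes), and taxonomic
#' consistency of all clones. Overall pass requires all four.
#'
#' @param report A [damage_report()] object.
#' @param blanks_negative Were all PCR blanks negative?
#' @param n_pcr Number of independent PCR amplifications performed.
#' @param clones_consistent Were all clones identified as the expected
#'   taxon?
#' @return A list of class `authenticity_summary`: `criteria` tibble
#'   `(criterion, pass)` and `overall`.
#' @export
authenticity_summary <- function(report, blanks_negative, n_pcr,
                                 clones_consistent) {
  damage_ok <- if (!report$undefined && report$total >= 4) {
    report$type2_fraction >= 0.5
  } else TRUE
  criteria <- tibble::tibble(
    criterion = c("blanks_negative", "independent_pcrs",
                  "deamination_biased_damage", "clone_identity_consistent"),
    pass = c(isTRUE(blanks_negative), n_pcr >= 2, damage_ok,
             isTRUE(clones_consistent))
  )
  structure(list(criteria = criteria, overall = all(criteria$pass)),
            class = "authenticity_summary")
}

#' @export
print.authenticity_summary <- function(x, ...) {
  cat("ancient-DNA authentication:",
      if (x$overall) "PASS" else "FAIL", "\n")
  for (i in seq_len(nrow(x$criteria))) {
    cat(sprintf("  [%s] %s\n", if (x$criteria$pass[i]) "ok" else "FAIL",
                x$criteria$criterion[i]))
  }
  invisible(x)
}
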
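#' Build an alignment tibble
#'
#' Alignments are tibbles with columns `label` and `sequence` (equal-length
#' strings over A/C/G/T/N/-). Validates lengths and label uniqueness.
#'
#' @param labels Character vector of unique record labels.
#' @param sequences Character vector of aligned sequences.
#' @return An alignment tibble.
#' @export
alignment <- function(labels, sequences) {
  stopifnot(length(labels) == length(sequences))
  if (anyDuplicated(labels)) stop("alignment labels must be unique", call. = FALSE)
  L <- nchar(sequences)
  if (length(unique(L)) > 1) {
    stop("all aligned sequences must have equal length", call. = FALSE)
  }
  tibble::tibble(label = unname(as.character(labels)),
                 sequence = unname(toupper(as.character(sequences))))
}

# Internal: alignment tibble -> character matrix (rows = records).
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequence, ""))
  rownames(m) <- aln$label
  m
}

#' Count substitution classes between two aligned sequences
#'
#' Sites where either symbol is not A/C/G/T (gaps, Ns) are excluded from
#' the comparable length and every count. Transitions are split into the
#' purine class P1 (A/G) and the pyrimidine class P2 (C/T); Q counts
#' transversions. Base frequencies are averaged over both sequences'
#' comparable sites.
#'
#' @param seq_a,seq_b Aligned sequences of equal length.
#' @return A one-row tibble `(L, P1, P2, Q, pi_A, pi_C, pi_G, pi_T)`.
#' @examples
#' pairwise_counts("ACGT", "GCGT")
#' @export
pairwise_counts <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) stop("sequences differ in length", call. = FALSE)
  bases <- c("A", "C", "G", "T")
  ok <- a %in% bases & b %in% bases
  a <- a[ok]; b <- b[ok]
  L <- length(a)
  diff <- a != b
  pur <- c("A", "G")
  P1 <- sum(diff & a %in% pur & b %in% pur)
  P2 <- sum(diff & !(a %in% pur) & !(b %in% pur))
  Q <- sum(diff) - P1 - P2
  freq <- (table(factor(a, bases)) + table(factor(b, bases))) / (2 * max(L, 1))
  tibble::tibble(L = L, P1 = P1, P2 = P2, Q = Q,
                 pi_A = as.numeric(freq["A"]), pi_C = as.numeric(freq["C"]),
                 pi_G = as.numeric(freq["G"]), pi_T = as.numeric(freq["T"]))
}

#' Tamura-Nei (TN93) distance from substitution counts
#'
#' Closed-form TN93 estimator on the proportions `P1/L`, `P2/L`, `Q/L` and
#' the averaged base frequencies. Saturated pairs (a non-positive logarithm
#' argument) yield `NA` with a warning rather than a clamped value.
#'
#' @param counts A tibble of pairwise counts as returned by
#'   [pairwise_counts()]; may have several rows.
#' @return Numeric vector of distances (substitutions/site).
#' @export
tn93_distance <- function(counts) {
  vapply(seq_len(nrow(counts)), function(i) {
    cc <- counts[i, ]
    if (cc$L <= 0) stop("no comparable sites", call. = FALSE)
    P1 <- cc$P1 / cc$L; P2 <- cc$P2 / cc$L; Q <- cc$Q / cc$L
    gR <- cc$pi_A + cc$pi_G; gY <- cc$pi_C + cc$pi_T
    k1 <- if (gR > 0) 2 * cc$pi_A * cc$pi_G / gR else 0
    k2 <- if (gY > 0) 2 * cc$pi_C * cc$pi_T / gY else 0
    k3 <- 2 * (gR * gY -
                 (if (gR > 0) cc$pi_A * cc$pi_G * gY / gR else 0) -
                 (if (gY > 0) cc$pi_C * cc$pi_T * gR / gY else 0))
    d <- 0
    if (k1 > 0) {
      a1 <- 1 - P1 / k1 - Q / (2 * gR)
      if (a1 <= 0) { warning("saturated pair: TN93 undefined", call. = FALSE); return(NA_real_) }
      d <- d - k1 * log(a1)
    } else if (P1 > 0) {
      warning("saturated pair: TN93 undefined", call. = FALSE); return(NA_real_)
    }
    if (k2 > 0) {
      a2 <- 1 - P2 / k2 - Q / (2 * gY)
      if (a2 <= 0) { warning("saturated pair: TN93 undefined", call. = FALSE); return(NA_real_) }
      d <- d - k2 * log(a2)
    } else if (P2 > 0) {
      warning("saturated pair: TN93 undefined", call. = FALSE); return(NA_real_)
    }
    if (gR > 0 && gY > 0) {
      a3 <- 1 - Q / (2 * gR * gY)
      if (a3 <= 0) { warning("saturated pair: TN93 undefined", call. = FALSE); return(NA_real_) }
      d <- d - k3 * log(a3)
    } else if (Q > 0) {
      warning("saturated pair: TN93 undefined", call. = FALSE); return(NA_real_)
    }
    d
  }, numeric(1))
}

# Internal: codon-position vector for a frame (position `frame` is codon
# position 1).
codon_positions <- function(L, frame) {
  stopifnot(frame %in% 1:3)
  ((seq_len(L) - frame) %% 3) + 1
}

#' Pairwise substitution-saturation series
#'
#' One row per unordered pair of records: TN93 distance and absolute
#' transition count, optionally excluding third codon positions. A
#' saturation verdict compares the slope of transitions against distance in
#' the upper distance quartile with the lower quartile: a plateau (upper
#' slope below half the lower slope) is called "saturated".
#'
#' @param aln An alignment tibble.
#' @param positions `"all"` or `"no_third"` (third codon positions
#'   excluded; requires `frame`).
#' @param frame Reading frame (1-3) used to locate third positions.
#' @return A tibble `(label_a, label_b, distance, transitions, defined)` of
#'   class `saturation_series` with attributes `verdict`,
#'   `slope_lower`, `slope_upper`.
#' @export
saturation_series <- function(aln, positions = c("all", "no_third"),
                              frame = NULL) {
  positions <- match.arg(positions)
  if (nrow(aln) < 2) stop("need >= 2 records", call. = FALSE)
  seqs <- aln$sequence
  if (positions == "no_third") {
    if (is.null(frame)) {
      stop("third-codon-excluded mode requires a reading frame", call. = FALSE)
    }
    cp <- codon_positions(nchar(seqs[1]), frame)
    keep <- cp != 3
    seqs <- vapply(strsplit(seqs, ""), function(ch)
      paste0(ch[keep], collapse = ""), character(1))
  }
  pairs <- utils::combn(nrow(aln), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    cts <- pairwise_counts(seqs[i1], seqs[i2])
    d <- suppressWarnings(tn93_distance(cts))
    tibble::tibble(label_a = aln$label[i1], label_b = aln$label[i2],
                   distance = d, transitions = cts$P1 + cts$P2,
                   defined = !is.na(d))
  })
  out <- dplyr::bind_rows(rows)
  ok <- out[out$defined, ]
  verdict <- NA_character_; sl <- c(NA_real_, NA_real_)
  if (nrow(ok) >= 8 && stats::sd(ok$distance) > 0) {
    qs <- stats::quantile(ok$distance, c(0.25, 0.75))
    lower <- ok[ok$distance <= qs[1], ]
    upper <- ok[ok$distance >= qs[2], ]
    if (nrow(lower) >= 3 && nrow(upper) >= 3 &&
        stats::sd(lower$distance) > 0 && stats::sd(upper$distance) > 0) {
      sl[1] <- stats::coef(stats::lm(transitions ~ distance, lower))[2]
      sl[2] <- stats::coef(stats::lm(transitions ~ distance, upper))[2]
      verdict <- if (sl[2] < 0.5 * sl[1]) "saturated" else "not saturated"
    }
  }
  attr(out, "verdict") <- verdict
  attr(out, "slope_lower") <- sl[1]
  attr(out, "slope_upper") <- sl[2]
  class(out) <- c("saturation_series", class(out))
  out
}

#' RY-recode third codon positions
#'
#' Collapses A/G to R (purine) and C/T to Y (pyrimidine) at third codon
#' positions, removing the fast, saturation-prone transition signal there;
#' other positions, Ns and gaps are untouched. Idempotent.
#'
#' @param aln An alignment tibble.
#' @param frame Reading frame (1-3).
#' @return The recoded alignment tibble.
#' @examples
#' ry_recode(alignment("x", "ATG"), frame = 1)
#' @export
ry_recode <- function(aln, frame = NULL) {
  if (is.null(frame)) stop("RY recoding requires a reading frame", call. = FALSE)
  cp <- codon_positions(nchar(aln$sequence[1]), frame)
  third <- cp == 3
  mat <- aln_matrix(aln)
  sub <- mat[, third, drop = FALSE]
  sub[sub %in% c("A", "G")] <- "R"
  sub[sub %in% c("C", "T")] <- "Y"
  mat[, third] <- sub
  tibble::tibble(label = aln$label,
                 sequence = unname(apply(mat, 1, paste0, collapse = "")))
}

#' Base-composition homogeneity test
#'
#' Chi-square homogeneity test on the taxa-by-base (A/C/G/T) count table,
#' excluding Ns and gaps; flags taxa with deviant composition. The degrees
#' of freedom are `(taxa - 1) * 3`.
#'
#' @param aln An alignment tibble with >= 2 records.
#' @return A list of class `base_composition_test`: `statistic`, `df`,
#'   `p_value` and a `deviations` tibble with per-taxon base frequencies
#'   and chi-square contributions.
#' @export
base_composition_test <- function(aln) {
  if (nrow(aln) < 2) stop("need >= 2 records", call. = FALSE)
  mat <- aln_matrix(aln)
  bases <- c("A", "C", "G", "T")
  counts <- t(apply(mat, 1, function(r) table(factor(r, bases))))
  zero <- rowSums(counts) == 0
  if (any(zero)) {
    stop("taxon with zero countable sites: ",
         paste(aln$label[zero], collapse = ", "), call. = FALSE)
  }
  use <- counts[, colSums(counts) > 0, drop = FALSE]
  E <- outer(rowSums(use), colSums(use)) / sum(use)
  statistic <- sum((use - E)^2 / E)
  df <- (nrow(aln) - 1) * 3
  dev <- tibble::tibble(
    label = aln$label,
    chi_contrib = rowSums((use - E)^2 / E)
  )
  freq <- counts / rowSums(counts)
  for (b in bases) dev[[b]] <- as.numeric(freq[, b])
  structure(list(statistic = statistic, df = df,
                 p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
                 deviations = dev),
            class = "base_composition_test")
}

#' @export
print.base_composition_test <- function(x, ...) {
  cat(sprintf("base-composition homogeneity: X2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Mitochondrial translation screen for nuclear copies (NUMts)
#'
#' Translates a protein-coding fragment under the vertebrate mitochondrial
#' genetic code and fails the screen if any stop codon appears in frame
#' (a genuine mid-gene mitochondrial fragment translates without stops;
#' note AGA/AGG are stops under this code).
#'
#' @param sequence Ungapped nucleotide sequence.
#' @param frame Reading frame in 1:3.
#' @return A list `(pass, stops)` where `stops` is a tibble
#'   `(codon_index, codon)` of offending codons.
#' @examples
#' mito_translation_screen("ATGTAAGCC", frame = 1)
#' @export
mito_translation_screen <- function(sequence, frame = 1) {
  stopifnot(frame %in% 1:3)
  s <- toupper(gsub("-", "", sequence))
  s <- substr(s, frame, nchar(s))
  n_codons <- nchar(s) %/% 3
  if (n_codons < 1) stop("sequence shorter than one codon", call. = FALSE)
  s <- substr(s, 1, 3 * n_codons)
  aa <- strsplit(as.character(Biostrings::translate(
    Biostrings::DNAString(s),
    genetic.code = Biostrings::getGeneticCode("2"),
    if.fuzzy.codon = "solve")), "")[[1]]
  stop_idx <- which(aa == "*")
  codons <- if (length(stop_idx)) {
    substring(s, 3 * stop_idx - 2, 3 * stop_idx)
  } else character(0)
  list(pass = length(stop_idx) == 0,
       stops = tibble::tibble(codon_index = stop_idx, codon = codons))
}
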
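#' Extract an alignment window by ungapped reference coordinates
#'
#' Coordinates are 1-based inclusive positions on the UNGAPPED reference
#' record; the returned window spans all alignment columns between the
#' columns of the start and end reference positions. Columns where the
#' reference carries a gap inside the window are retained and flagged.
#'
#' @param aln An alignment tibble.
#' @param reference Label of the reference record.
#' @param start,end 1-based inclusive ungapped reference coordinates.
#' @return An alignment tibble restricted to the window, with attribute
#'   `fragment_info`: a tibble `(column, alignment_column, ref_position,
#'   ref_gap)` mapping window columns back to the source alignment and to
#'   reference coordinates.
#' @examples
#' a <- alignment(c("ref", "q"), c("A-CGT", "AACGT"))
#' extract_fragment(a, "ref", 2, 3)
#' @export
extract_fragment <- function(aln, reference, start, end) {
  i <- match(reference, aln$label)
  if (is.na(i)) stop("reference record not found: ", reference, call. = FALSE)
  ref <- strsplit(aln$sequence[i], "")[[1]]
  ungapped <- cumsum(ref != "-")
  n_ref <- max(ungapped)
  if (start < 1 || end > n_ref || start > end) {
    stop("coordinates ", start, "-", end,
         " outside ungapped reference length ", n_ref, call. = FALSE)
  }
  col_start <- which(ungapped == start & ref != "-")[1]
  col_end <- which(ungapped == end & ref != "-")[1]
  cols <- col_start:col_end
  mat <- aln_matrix(aln)[, cols, drop = FALSE]
  out <- tibble::tibble(label = aln$label,
                        sequence = unname(apply(mat, 1, paste0, collapse = "")))
  attr(out, "fragment_info") <- tibble::tibble(
    column = seq_along(cols),
    alignment_column = cols,
    ref_position = ifelse(ref[cols] == "-", NA_integer_,
                          as.integer(ungapped[cols])),
    ref_gap = ref[cols] == "-"
  )
  out
}

# Internal: per-column fixed state of each entity, NA when members differ
# or any member carries N/-; returns entities x columns character matrix.
entity_fixed_states <- function(mat, entities) {
  ents <- sort(unique(entities))
  bases <- c("A", "C", "G", "T")
  out <- matrix(NA_character_, length(ents), ncol(mat),
                dimnames = list(as.character(ents), NULL))
  for (e in seq_along(ents)) {
    sub <- mat[entities == ents[e], , drop = FALSE]
    first <- sub[1, ]
    fixed <- colSums(sub != rep(first, each = nrow(sub))) == 0 &
      first %in% bases
    out[e, fixed] <- first[fixed]
  }
  out
}

#' Derive pure diagnostic characters per entity
#'
#' A pure diagnostic is an alignment column state shared by every member of
#' one entity and carried by no member of any other entity. Columns where
#' any member of the candidate entity has N or a gap are skipped for that
#' entity.
#'
#' @param aln An alignment tibble (typically a fragment from
#'   [extract_fragment()]).
#' @param partition A partition tibble `(label, entity)` covering every
#'   alignment record.
#' @return A tibble of class `diagnostic_rules`:
#'   `(entity, column, ref_position, state)`, with attributes `entities`
#'   and `n_columns`.
#' @export
find_diagnostics <- function(aln, partition) {
  idx <- match(aln$label, partition$label)
  if (anyNA(idx)) {
    stop("records without entity assignment: ",
         paste(aln$label[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  entities <- partition$entity[idx]
  if (!all(partition$entity %in% entities)) {
    stop("entity with zero members in the alignment", call. = FALSE)
  }
  mat <- aln_matrix(aln)
  info <- attr(aln, "fragment_info")
  ref_pos <- if (is.null(info)) seq_len(ncol(mat)) else info$ref_position
  ents <- sort(unique(entities))
  rows <- list()
  for (e in ents) {
    members <- mat[entities == e, , drop = FALSE]
    others <- mat[entities != e, , drop = FALSE]
    first <- members[1, ]
    fixed <- colSums(members != rep(first, each = nrow(members))) == 0 &
      first %in% c("A", "C", "G", "T")
    absent <- colSums(others == rep(first, each = nrow(others))) == 0
    hit <- which(fixed & absent)
    if (length(hit)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        entity = e, column = hit,
        ref_position = ref_pos[hit], state = first[hit])
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(entity = ents[0], column = integer(),
                   ref_position = integer(), state = character())
  attr(out, "entities") <- ents
  attr(out, "n_columns") <- ncol(mat)
  class(out) <- c("diagnostic_rules", class(out))
  out
}

#' Pairwise discriminability of entities over an alignment window
#'
#' Entity pair (i, j) is discriminable when some column carries one state
#' fixed in every member of i and a different state fixed in every member
#' of j (neither involving N or gaps).
#'
#' @inheritParams find_diagnostics
#' @return A symmetric logical matrix over entities (diagonal `NA`).
#' @export
discriminability_matrix <- function(aln, partition) {
  idx <- match(aln$label, partition$label)
  if (anyNA(idx)) stop("records without entity assignment", call. = FALSE)
  entities <- partition$entity[idx]
  fixed <- entity_fixed_states(aln_matrix(aln), entities)
  k <- nrow(fixed)
  out <- matrix(NA, k, k, dimnames = list(rownames(fixed), rownames(fixed)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      out[i, j] <- any(!is.na(fixed[i, ]) & !is.na(fixed[j, ]) &
                         fixed[i, ] != fixed[j, ])
    }
  }
  out
}

#' Classify a query sequence against diagnostic rules
#'
#' Scores each entity by the number of its diagnostic rules whose
#' (column, state) the query matches and assigns the unique top scorer;
#' ties and all-zero scores are reported as `"ambiguous"`.
#'
#' @param query Query sequence aligned to the ruleset's fragment
#'   coordinates (same number of columns).
#' @param rules A `diagnostic_rules` tibble from [find_diagnostics()].
#' @return A list of class `barcode_classification`: `assigned` (entity id
#'   as character, or `"ambiguous"`), `scores` tibble
#'   `(entity, n_rules, matched)`, `margin` (best minus second-best score)
#'   and `fraction_matched` of the best entity's rules.
#' @export
classify_query <- function(query, rules) {
  q <- strsplit(toupper(query), "")[[1]]
  if (length(q) != attr(rules, "n_columns")) {
    stop("query length ", length(q), " does not match fragment width ",
         attr(rules, "n_columns"), call. = FALSE)
  }
  ents <- attr(rules, "entities")
  scores <- tibble::tibble(
    entity = ents,
    n_rules = vapply(ents, function(e) sum(rules$entity == e), integer(1)),
    matched = vapply(ents, function(e) {
      r <- rules[rules$entity == e, ]
      sum(q[r$column] == r$state)
    }, integer(1))
  )
  ord <- order(scores$matched, decreasing = TRUE)
  best <- scores$matched[ord[1]]
  second <- if (length(ord) > 1) scores$matched[ord[2]] else 0L
  margin <- best - second
  ambiguous <- best == 0 || margin == 0
  structure(list(
    assigned = if (ambiguous) "ambiguous" else as.character(scores$entity[ord[1]]),
    scores = scores,
    margin = margin,
    fraction_matched = if (scores$n_rules[ord[1]] > 0)
      best / scores$n_rules[ord[1]] else NA_real_
  ), class = "barcode_classification")
}

#' @export
print.barcode_classification <- function(x, ...) {
  cat("barcode classification:", x$assigned,
      sprintf("(margin %d, %.0f%% of best entity's rules matched)\n",
              x$margin, 100 * x$fraction_matched))
  invisible(x)
}
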
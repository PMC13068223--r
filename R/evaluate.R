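# Circular-aware accuracy evaluation against a reference plasmid.
#
# Queries are aligned against the doubled reference in both orientations;
# the alignment is decomposed into at most two segments in reference
# coordinates (the primary plus the wrap-around secondary), whose counts are
# summed. Identity is 100 * matches / (matches + mismatches + indels), the
# standard long-read accuracy measure, and converts to a Phred-scaled Q as
# -10*log10(error rate).

#' Align a query to a circular reference
#'
#' @param query DNA string (a subread, consensus read, or polished
#'   sequence).
#' @param reference DNA string: one full turn of the circular reference.
#' @param min_identity alignments below this identity percent raise an
#'   `unalignable` error (default 60).
#' @return an object of class `alignment_stats`: counts `matches`,
#'   `mismatches`, `insertions` (query bases absent from the reference),
#'   `deletions` (reference bases absent from the query), `segments` (1 or 2
#'   `(query_start, query_end, ref_start, ref_end)` rows in reference
#'   coordinates mod reference length), plus the orientation and the raw
#'   edit script for positional profiling.
#' @export
align_circular <- function(query, reference, min_identity = 60) {
  stopifnot(nchar(query) >= 1, nchar(reference) >= 1)
  L <- nchar(reference)
  doubled <- paste0(reference, reference)
  a <- align_evidence(query, doubled, both_orientations = TRUE)
  ops <- strsplit(a$ops, "", fixed = TRUE)[[1]]
  m <- sum(ops == "M"); mm <- sum(ops == "X")
  ins <- sum(ops == "I"); del <- sum(ops == "D")
  ident <- 100 * m / (m + mm + ins + del)
  if (ident < min_identity)
    stop(condition_error("unalignable", sprintf(
      "best circular alignment identity %.1f%% below %.1f%%",
      ident, min_identity)))
  d <- decode_ops(a$ops, a$t_start)
  tcon <- d$op != "I"
  seg_break <- which(tcon & d$tpos == L + 1L)
  segments <- list()
  add_seg <- function(sel) {
    if (!any(sel)) return()
    tp <- d$tpos[sel & tcon]
    qp <- d$qpos[sel & d$op != "D"]
    segments[[length(segments) + 1L]] <<- c(
      query_start = if (length(qp)) min(qp) else NA_integer_,
      query_end = if (length(qp)) max(qp) else NA_integer_,
      ref_start = ((min(tp) - 1L) %% L) + 1L,
      ref_end = ((max(tp) - 1L) %% L) + 1L)
  }
  idx <- seq_along(d$op)
  if (length(seg_break) && a$t_start <= L) {
    add_seg(idx < seg_break[1])
    add_seg(idx >= seg_break[1])
  } else add_seg(idx >= 1L)
  structure(list(matches = m, mismatches = mm, insertions = ins,
                 deletions = del, segments = segments,
                 orientation = if (a$rc) "-" else "+",
                 ops = a$ops, t_start = a$t_start,
                 reference_length = L),
            class = "alignment_stats")
}

#' Alignment identity in percent
#'
#' `100 * matches / (matches + mismatches + insertions + deletions)`.
#'
#' @param stats an [align_circular] result.
#' @return identity percent.
#' @export
identity_percent <- function(stats) {
  total <- stats$matches + stats$mismatches + stats$insertions +
    stats$deletions
  stopifnot(total > 0)
  100 * stats$matches / total
}

#' Convert identity percent to a Phred-scaled Q
#'
#' `Q = -10 * log10(1 - identity/100)`; a perfect identity is capped at
#' Q93. The conventional displayed value is the floor (99.86 percent gives
#' Q28.54, displayed Q28).
#'
#' @param identity_percent identity in (0, 100].
#' @return Phred-scaled Q as a float.
#' @export
q_from_identity <- function(identity_percent) {
  stopifnot(identity_percent > 0, identity_percent <= 100)
  if (identity_percent >= 100) return(93)
  min(93, -10 * log10(1 - identity_percent / 100))
}

#' Displayed (integer) Q for an identity percent
#'
#' @param identity_percent identity in (0, 100].
#' @return `floor(q_from_identity(identity_percent))` as integer.
#' @export
q_display <- function(identity_percent) {
  as.integer(floor(q_from_identity(identity_percent)))
}

#' Is a sequence a full-length, error-free copy of a circular reference?
#'
#' True iff the query length exactly matches the reference length and the
#' circular alignment has zero mismatches and zero indels; rotation- and
#' strand-invariant.
#'
#' @param query,reference DNA strings.
#' @return logical flag.
#' @export
is_full_length_error_free <- function(query, reference) {
  if (nchar(query) != nchar(reference)) return(FALSE)
  st <- tryCatch(align_circular(query, reference),
                 unalignable = function(e) NULL)
  !is.null(st) && st$mismatches == 0L && st$insertions == 0L &&
    st$deletions == 0L
}

#' Per-position error profile over a circular reference
#'
#' Accumulates, per reference position, the numbers of aligned queries with
#' a match, a mismatch, a deletion, or an insertion immediately following
#' that position (insertions are attributed to the reference position they
#' follow, circularly).
#'
#' @param queries character vector (or list) of query sequences.
#' @param reference DNA string.
#' @return a data.frame with `pos`, `ref_base`, `n_match`, `n_mismatch`,
#'   `n_ins`, `n_del`; unalignable queries are skipped with a warning.
#' @export
positional_error_profile <- function(queries, reference) {
  stopifnot(length(queries) >= 1)
  L <- nchar(reference)
  acc <- matrix(0L, nrow = L, ncol = 4L,
                dimnames = list(NULL, c("n_match", "n_mismatch",
                                        "n_ins", "n_del")))
  for (q in queries) {
    st <- tryCatch(align_circular(q, reference),
                   unalignable = function(e) NULL)
    if (is.null(st)) { warning("skipping unalignable query"); next }
    d <- decode_ops(st$ops, st$t_start)
    refpos <- ((d$tpos - 1L) %% L) + 1L
    refpos[d$tpos == 0L] <- L  # insertion before the start wraps around
    for (col in 1:4) {
      sel <- d$op == c("M", "X", "I", "D")[col]
      if (col == 3L) {
        # count at most one insertion event per (query, position)
        p <- unique(refpos[sel])
      } else p <- refpos[sel]
      if (length(p)) acc[, col] <- acc[, col] + tabulate(p, L)
    }
  }
  data.frame(pos = seq_len(L),
             ref_base = strsplit(reference, "", fixed = TRUE)[[1]],
             acc)
}

#' Per-read evaluation report
#'
#' @param queries named character vector of query sequences (names become
#'   read ids).
#' @param reference DNA string.
#' @return data.frame with one row per query: length, alignment counts,
#'   identity, Q, and the full-length error-free flag; unalignable queries
#'   get NA counts.
#' @export
evaluate_reads <- function(queries, reference) {
  ids <- names(queries)
  if (is.null(ids)) ids <- paste0("query", seq_along(queries))
  rows <- lapply(seq_along(queries), function(i) {
    st <- tryCatch(align_circular(queries[[i]], reference),
                   unalignable = function(e) NULL)
    if (is.null(st))
      return(data.frame(read_id = ids[i], length = nchar(queries[[i]]),
                        matches = NA, mismatches = NA, insertions = NA,
                        deletions = NA, identity = NA, q = NA,
                        full_length_error_free = FALSE))
    ident <- identity_percent(st)
    data.frame(read_id = ids[i], length = nchar(queries[[i]]),
               matches = st$matches, mismatches = st$mismatches,
               insertions = st$insertions, deletions = st$deletions,
               identity = ident, q = q_from_identity(ident),
               full_length_error_free =
                 nchar(queries[[i]]) == nchar(reference) &&
                 st$mismatches + st$insertions + st$deletions == 0L)
  })
  do.call(rbind, rows)
}
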
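# Splint-free tandem-repeat boundary detection and subread splitting.
#
# Instead of a known splint/adapter, an anchor stretch is copied from a few
# hundred bases into the read itself; its approximate recurrences reveal the
# repeat period, and the read is split at the anchor start positions. All
# coordinates are 1-based and intervals closed, the R convention.

#' Extract the anchor from a raw read
#'
#' @param read a [raw_read].
#' @param offset number of bases skipped before the anchor (default 250, to
#'   avoid low-quality read starts); the anchor starts at `offset + 1`.
#' @param anchor_length anchor length in bases (default 200).
#' @return an object of class `anchor` with fields `sequence` and
#'   `source_start` (1-based start in the read).
#' @export
extract_anchor <- function(read, offset = 250L, anchor_length = 200L) {
  if (nchar(read$sequence) < offset + anchor_length)
    stop(condition_error("read_too_short", sprintf(
      "read '%s' (%d bases) shorter than offset + anchor length (%d)",
      read$read_id, nchar(read$sequence), offset + anchor_length)))
  structure(list(sequence = substr(read$sequence, offset + 1L,
                                   offset + anchor_length),
                 source_start = offset + 1L,
                 anchor_length = as.integer(anchor_length)),
            class = "anchor")
}

#' Locate all anchor occurrences in a read
#'
#' Semi-global edit-distance scan for non-overlapping approximate occurrences
#' of the anchor, accepted up to `max_error_fraction` of the anchor length.
#' The source occurrence itself is always among the hits. Fewer than 2 hits
#' means the repeat period cannot be estimated and the boundaries are flagged
#' unusable.
#'
#' @param read a [raw_read].
#' @param anchor an [extract_anchor] result.
#' @param max_error_fraction maximum edit distance as a fraction of the
#'   anchor length (default 0.30).
#' @return an object of class `repeat_boundaries` with `hit_positions`
#'   (1-based, strictly increasing anchor start positions),
#'   `repeat_length_estimate` (median spacing) and `usable`.
#' @export
locate_anchor <- function(read, anchor, max_error_fraction = 0.30) {
  max_dist <- as.integer(floor(max_error_fraction * anchor$anchor_length))
  hits <- cpp_anchor_scan(anchor$sequence, read$sequence, max_dist)
  starts <- hits[, "start"]
  usable <- length(starts) >= 2L
  structure(list(hit_positions = starts,
                 hit_dists = hits[, "dist"],
                 repeat_length_estimate =
                   if (usable) median(diff(starts)) else NA_real_,
                 usable = usable,
                 anchor_length = anchor$anchor_length),
            class = "repeat_boundaries")
}

#' Split a read into subreads at its repeat boundaries
#'
#' One full subread per consecutive hit pair; the prefix before the first hit
#' and the suffix from the last hit on become partial subreads when they are
#' at least `partial_min_fraction` of the estimated repeat length, else they
#' are dropped. Partial subreads longer than the repeat estimate are chunked
#' at repeat-length multiples so each piece is a contiguous stretch of at
#' most one repeat unit. Full subreads carry ids `<parent>_<i>`, partials
#' `<parent>_<i>_p`.
#'
#' @param read a [raw_read].
#' @param boundaries usable [locate_anchor] boundaries.
#' @param partial_min_fraction retention threshold for terminal flanks as a
#'   fraction of the repeat length estimate (default 0.20).
#' @return list of `subread` objects (fields `parent_id`, `subread_id`,
#'   `index`, `sequence`, `qualities`, `is_partial`, `mean_q`).
#' @export
split_into_subreads <- function(read, boundaries, partial_min_fraction = 0.20) {
  stopifnot(isTRUE(boundaries$usable))
  h <- boundaries$hit_positions
  est <- boundaries$repeat_length_estimate
  n <- nchar(read$sequence)
  min_len <- partial_min_fraction * est

  slice <- function(from, to, index, partial, part_tag = "") {
    seq <- substr(read$sequence, from, to)
    qual <- read$qualities[from:to]
    structure(list(parent_id = read$read_id,
                   subread_id = sprintf("%s_%d%s", read$read_id, index,
                                        if (partial) "_p" else ""),
                   index = index, sequence = seq, qualities = qual,
                   is_partial = partial,
                   mean_q = mean_read_q(qual)$mean_q),
              class = "subread")
  }

  out <- list()
  idx <- 0L
  # prefix flank (tail of a repeat unit, ends at the first boundary)
  if (h[1] - 1L >= min_len)
    out <- c(out, list(slice(1L, h[1] - 1L, idx, TRUE)))
  for (i in seq_len(length(h) - 1L)) {
    idx <- idx + 1L
    out <- c(out, list(slice(h[i], h[i + 1] - 1L, idx, FALSE)))
  }
  # suffix flank from the last boundary; chunk at repeat-length multiples
  from <- h[length(h)]
  while (from <= n) {
    to <- min(n, from + round(est) - 1L)
    if (to - from + 1L >= min_len) {
      idx <- idx + 1L
      out <- c(out, list(slice(from, to, idx, TRUE)))
    }
    from <- to + 1L
  }
  out
}

#' Check full subreads for length consistency
#'
#' High length variability among the full subreads of one read indicates
#' faulty splitting (for example an internal tandem duplication causing the
#' anchor to recur at sub-unit spacing); such reads are excluded from
#' consensus calling.
#'
#' @param subreads list of subreads from [split_into_subreads].
#' @param tolerance_fraction allowed deviation from the median full-subread
#'   length (default 0.05).
#' @return TRUE (pass) or FALSE (fail).
#' @export
length_consistency_check <- function(subreads, tolerance_fraction = 0.05) {
  lens <- vapply(subreads, function(s) nchar(s$sequence), numeric(1))
  full <- !vapply(subreads, `[[`, logical(1), "is_partial")
  stopifnot(sum(full) >= 1L)
  lens <- lens[full]
  med <- median(lens)
  all(abs(lens - med) <= tolerance_fraction * med)
}
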
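# Per-read consensus calling: rough center-star consensus over the full
# subreads of one concatemer read, then a polish pass over all subreads
# (partial flanks included as polishing evidence only).
#
# The polisher is a quality-aware pileup caller: each evidence read is
# pairwise-aligned to the template (global in the evidence, local in the
# template); per template column the plurality symbol among aligned evidence
# wins (base, deletion, or inserted run), with ties broken toward the
# template; homopolymer runs are resolved jointly by a weighted median of
# observed run lengths. This reproduces the coverage-driven accuracy
# behaviour of window/POA polishers at contract level without replicating
# any particular tool's internals.

#' Quality-aware pileup polishing of a template sequence
#'
#' @param template DNA string to polish.
#' @param evidence list of evidence reads; each needs `sequence`,
#'   and `mean_q` (Phred float) when `weighting = "quality"`.
#' @param weighting `"uniform"` (weight 1 per read) or `"quality"` (weight
#'   `1 - 10^(-mean_q/10)` per read).
#' @param both_orientations align each evidence read in both orientations
#'   and keep the better one.
#' @param max_evidence_error an evidence read is dropped when its edit
#'   distance to the template exceeds this fraction of its length.
#' @param hp_min_run minimum template homopolymer run length for joint
#'   run-length resolution.
#' @return `list(sequence, coordinate_map, n_evidence)`. `coordinate_map[t]`
#'   is the output position of the last character emitted for template
#'   position `t` (a monotone template-to-output mapping used to trim
#'   circular padding).
#' @export
polish_template <- function(template, evidence,
                            weighting = c("uniform", "quality"),
                            both_orientations = FALSE,
                            max_evidence_error = 0.40, hp_min_run = 4L) {
  weighting <- match.arg(weighting)
  L <- nchar(template)
  stopifnot(L >= 1, length(evidence) >= 1)
  tch <- strsplit(template, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  # template homopolymer-run structure, used to left-normalize indel
  # placements so that equivalent-cost alignments from different evidence
  # reads (and orientations) vote at one canonical position
  run_id <- cumsum(c(TRUE, tch[-1L] != tch[-L]))
  run_start <- which(c(TRUE, tch[-1L] != tch[-L]))[run_id]

  # shift an inserted string left while it can equivalently attach one
  # position earlier (its last character equals the template base there)
  normalize_insertion <- function(p, s) {
    k <- nchar(s)
    while (p >= 1L && substr(s, k, k) == tch[p]) {
      s <- paste0(tch[p], substr(s, 1L, k - 1L))
      p <- p - 1L
    }
    list(pos = p, str = s)
  }

  base_w <- numeric(4L * L)
  del_w <- numeric(L)
  cov_add <- numeric(L + 2L)
  ins_pos <- integer(0); ins_str <- character(0); ins_w <- numeric(0)
  aligned <- vector("list", length(evidence))
  n_used <- 0L

  for (ev in evidence) {
    n <- nchar(ev$sequence)
    if (n < 5L) next
    a <- align_evidence(ev$sequence, template, both_orientations)
    if (a$dist > max_evidence_error * n) next
    w <- if (weighting == "quality")
      max(1e-6, 1 - 10^(-ev$mean_q / 10)) else 1
    d <- decode_ops(a$ops, a$t_start)
    ech <- strsplit(a$oriented_seq, "", fixed = TRUE)[[1]]

    is_mx <- d$op == "M" | d$op == "X"
    if (any(is_mx)) {
      eb <- ech[d$qpos[is_mx]]
      tp <- d$tpos[is_mx]
      bi <- match(eb, bases)          # NA for N: never votes
      ok <- !is.na(bi)
      if (any(ok))
        base_w <- base_w + w * tabulate((tp[ok] - 1L) * 4L + bi[ok], 4L * L)
    }
    is_d <- d$op == "D"
    if (any(is_d)) {
      # deleting any one base of a run is the same event: vote leftmost
      del_w <- del_w + w * tabulate(run_start[d$tpos[is_d]], L)
    }
    cov_add[a$t_start] <- cov_add[a$t_start] + w
    cov_add[a$t_end + 1L] <- cov_add[a$t_end + 1L] - w

    ev_ins <- list()
    is_i <- d$op == "I"
    if (any(is_i)) {
      r <- rle(is_i)
      rend <- cumsum(r$lengths)
      rstart <- rend - r$lengths + 1L
      for (k in which(r$values)) {
        qr <- d$qpos[rstart[k]:rend[k]]
        s <- gsub("N", "", paste(ech[qr], collapse = ""), fixed = TRUE)
        p <- d$tpos[rstart[k]]
        if (!nchar(s)) next
        nz <- normalize_insertion(p, s)
        if (nz$pos >= 1L) {
          ins_pos <- c(ins_pos, nz$pos)
          ins_str <- c(ins_str, nz$str)
          ins_w <- c(ins_w, w)
          ev_ins[[length(ev_ins) + 1L]] <- nz
        }
      }
    }
    n_used <- n_used + 1L
    aligned[[n_used]] <- list(dec = d, ech = ech, w = w,
                              t_start = a$t_start, t_end = a$t_end,
                              ins_runs = ev_ins)
  }
  if (n_used == 0L)
    stop(condition_error("polish_failed",
                         "no evidence read aligned to the template"))
  aligned <- aligned[seq_len(n_used)]
  cov <- cumsum(cov_add)[seq_len(L)]

  # per-column plurality among {A, C, G, T, deletion}; ties -> template
  bm <- matrix(base_w, nrow = 4L)
  maxw <- pmax(bm[1L, ], bm[2L, ], bm[3L, ], bm[4L, ], del_w)
  wk <- max.col(cbind(t(bm), del_w), ties.method = "first")
  emit <- c(bases, "")[wk]
  tidx <- match(tch, bases)
  tw <- rep(-1, L)
  has_t <- !is.na(tidx)
  tw[has_t] <- bm[cbind(tidx[has_t], which(has_t))]
  use_t <- cov <= 1e-12 | (has_t & tw >= maxw - 1e-9)
  emit[use_t] <- tch[use_t]

  # inserted runs: emitted after position p when the top inserted string
  # outweighs the spanning evidence that saw no insertion there
  ins_emit <- character(L)
  if (length(ins_pos)) {
    for (p in unique(ins_pos)) {
      at <- ins_pos == p
      wsum <- tapply(ins_w[at], ins_str[at], sum)
      total <- sum(ins_w[at])
      best <- which.max(wsum)
      if (wsum[best] > (cov[p] - total) + 1e-9)
        ins_emit[p] <- names(wsum)[best]
    }
  }

  # joint homopolymer run-length resolution
  r <- rle(tch)
  rend <- cumsum(r$lengths)
  rstart <- rend - r$lengths + 1L
  for (k in which(r$lengths >= hp_min_run & r$values %in% bases)) {
    s <- rstart[k]; e <- rend[k]; B <- r$values[k]
    win <- max(1L, s - 1L):e
    # a winning insertion of foreign bases inside the run means the region
    # is not a clean homopolymer (e.g. the template fused two runs by a
    # deletion); leave such runs to the column-wise calls
    pure <- function(x) gsub(B, "", x, fixed = TRUE) == ""
    if (any(nzchar(ins_emit[win]) & !pure(ins_emit[win]))) next
    lens <- numeric(0); ws <- numeric(0)
    for (al in aligned) {
      if (al$t_start > max(1L, s - 1L) || al$t_end < min(L, e + 1L)) next
      d <- al$dec
      n_mx <- sum((d$op == "M" | d$op == "X") & d$tpos >= s & d$tpos <= e &
                    al$ech[d$qpos] == B)
      n_i <- 0L
      for (ir in al$ins_runs)
        if (ir$pos >= s - 1L && ir$pos <= e && pure(ir$str))
          n_i <- n_i + nchar(ir$str)
      lens <- c(lens, n_mx + n_i)
      ws <- c(ws, al$w)
    }
    if (!length(lens)) next
    med <- weighted_median_runlen(lens, ws, e - s + 1L)
    emit[s] <- strrep(B, med)
    if (e > s) emit[(s + 1L):e] <- ""
    ins_emit[win][pure(ins_emit[win])] <- ""  # folded into the run vote
  }

  colstr <- paste0(emit, ins_emit)
  out_end <- cumsum(nchar(colstr))
  list(sequence = paste(colstr, collapse = ""),
       coordinate_map = as.integer(out_end),
       n_evidence = n_used)
}

# Weighted median of observed homopolymer run lengths. When the median is an
# interval (even split), the template's own run length is kept if it lies
# inside the interval (conservative: never change without majority
# evidence), else the lower bound is used.
weighted_median_runlen <- function(lens, ws, template_len) {
  o <- order(lens)
  lens <- lens[o]; ws <- ws[o]
  cw <- cumsum(ws); W <- sum(ws)
  i <- which(cw >= W / 2 - 1e-12)[1]
  lo <- lens[i]
  hi <- if (abs(cw[i] - W / 2) < 1e-9 && i < length(lens)) lens[i + 1] else lo
  if (template_len >= lo && template_len <= hi) as.integer(template_len)
  else as.integer(lo)
}

#' Rough consensus of the full subreads of one read
#'
#' Center-star progressive alignment: the full subread whose length is
#' closest to the median is the center; all full subreads (center included)
#' are aligned to it and a column-wise plurality call is emitted. With a
#' single full subread it is returned unchanged.
#'
#' @param subreads list of subreads; partial flanks are ignored here.
#' @return the consensus DNA string.
#' @export
rough_consensus <- function(subreads) {
  full <- Filter(function(s) !s$is_partial, subreads)
  stopifnot(length(full) >= 1L)
  if (length(full) == 1L) return(full[[1]]$sequence)
  lens <- vapply(full, function(s) nchar(s$sequence), numeric(1))
  center <- full[[which.min(abs(lens - median(lens)))]]
  polish_template(center$sequence, full, weighting = "uniform",
                  both_orientations = FALSE)$sequence
}

#' Default configuration for consensus calling
#'
#' @param anchor_offset bases skipped before the anchor (default 250).
#' @param anchor_length anchor length (default 200).
#' @param max_error_fraction anchor-match edit-distance tolerance (default
#'   0.30 of the anchor length).
#' @param tolerance_fraction full-subread length-consistency tolerance
#'   (default 0.05).
#' @param partial_min_fraction terminal-flank retention threshold (default
#'   0.20 of the repeat length).
#' @return a named list of parameters.
#' @export
consensus_config <- function(anchor_offset = 250L, anchor_length = 200L,
                             max_error_fraction = 0.30,
                             tolerance_fraction = 0.05,
                             partial_min_fraction = 0.20) {
  list(anchor_offset = anchor_offset, anchor_length = anchor_length,
       max_error_fraction = max_error_fraction,
       tolerance_fraction = tolerance_fraction,
       partial_min_fraction = partial_min_fraction)
}

#' Build one consensus read from a raw concatemer read
#'
#' Composes anchor extraction, anchor location, subread splitting, the
#' length-consistency guard, rough consensus and a uniform-weight polish
#' pass with all subreads (partial flanks included) as evidence. Reads that
#' cannot be processed return a skip record rather than an error.
#'
#' @param read a [raw_read].
#' @param config a [consensus_config].
#' @return an object of class `consensus_read` (fields `read_id`,
#'   `sequence`, `subread_count` counting full subreads only,
#'   `mean_subread_q`, and the contributing `subreads`), or an object of
#'   class `consensus_skip` with a `reason` in `too_short`, `anchor_hits`,
#'   `length_inconsistent`, `polish_failed`.
#' @export
make_consensus_read <- function(read, config = consensus_config()) {
  skip <- function(reason)
    structure(list(read_id = read$read_id, reason = reason),
              class = "consensus_skip")
  anchor <- tryCatch(
    extract_anchor(read, config$anchor_offset, config$anchor_length),
    read_too_short = function(e) NULL)
  if (is.null(anchor)) return(skip("too_short"))
  b <- locate_anchor(read, anchor, config$max_error_fraction)
  if (!b$usable) return(skip("anchor_hits"))
  subs <- split_into_subreads(read, b, config$partial_min_fraction)
  if (!length_consistency_check(subs, config$tolerance_fraction))
    return(skip("length_inconsistent"))
  rough <- rough_consensus(subs)
  pol <- tryCatch(
    polish_template(rough, subs, weighting = "uniform"),
    polish_failed = function(e) NULL)
  if (is.null(pol)) return(skip("polish_failed"))
  full_n <- sum(!vapply(subs, `[[`, logical(1), "is_partial"))
  p <- mean(vapply(subs, function(s)
    mean_read_q(s$qualities)$mean_error_prob, numeric(1)))
  structure(list(read_id = read$read_id, sequence = pol$sequence,
                 subread_count = full_n,
                 mean_subread_q = -10 * log10(p),
                 subreads = subs),
            class = "consensus_read")
}

#' @export
print.consensus_read <- function(x, ...) {
  cat(sprintf("<consensus_read %s: %d bases, %d subreads, mean subread Q %.2f>\n",
              x$read_id, nchar(x$sequence), x$subread_count,
              x$mean_subread_q))
  invisible(x)
}

#' Write consensus reads as FASTA
#'
#' Headers encode coverage and quality as
#' `<read_id>_<subread_count>_<mean_q>` so downstream ranking needs no
#' sidecar file.
#'
#' @param consensus_reads list of `consensus_read` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_consensus_fasta <- function(consensus_reads, path) {
  seqs <- vapply(consensus_reads, `[[`, character(1), "sequence")
  names(seqs) <- vapply(consensus_reads, function(x)
    format_consensus_header(x$read_id, x$subread_count, x$mean_subread_q),
    character(1))
  write_fasta(seqs, path)
}

#' Read consensus reads from FASTA
#'
#' @param path FASTA written by [write_consensus_fasta].
#' @return list of `consensus_read` objects (without subreads).
#' @export
read_consensus_fasta <- function(path) {
  seqs <- read_fasta(path)
  lapply(seq_along(seqs), function(i) {
    h <- parse_consensus_header(names(seqs)[i])
    structure(list(read_id = h$read_id, sequence = unname(seqs[i]),
                   subread_count = h$subread_count,
                   mean_subread_q = h$mean_q, subreads = NULL),
              class = "consensus_read")
  })
}

#' Write subreads as FASTQ
#'
#' @param subreads list of subreads (from [split_into_subreads] or collected
#'   from `consensus_read$subreads`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_subreads_fastq <- function(subreads, path) {
  write_fastq(lapply(subreads, function(s)
    raw_read(s$subread_id, s$sequence, s$qualities)), path)
}

#' Read subreads back from FASTQ
#'
#' Subread ids follow `<parent>_<index>` with partials suffixed `_p`.
#'
#' @param path FASTQ written by [write_subreads_fastq].
#' @return list of subread objects.
#' @export
read_subreads_fastq <- function(path) {
  lapply(read_fastq(path), function(r) {
    partial <- grepl("_p$", r$read_id)
    parent <- sub("_[0-9]+(_p)?$", "", r$read_id)
    index <- as.integer(sub("^.*_([0-9]+)(_p)?$", "\\1", r$read_id))
    structure(list(parent_id = parent, subread_id = r$read_id,
                   index = index, sequence = r$sequence,
                   qualities = r$qualities, is_partial = partial,
                   mean_q = mean_read_q(r$qualities)$mean_q),
              class = "subread")
  })
}
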
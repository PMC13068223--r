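# Length-histogram demultiplexing and circular polishing of pooled consensus
# reads into one accurate full-length sequence per plasmid species.
#
# Pipeline per peak: rank member consensus reads by (subread coverage, mean
# subread Q); rank peak subreads by Q and keep the top n; for each of the
# top `iterations` templates: pad circularly (append the first half), polish
# twice (uniform, then quality-weighted with homopolymer run-length voting),
# trim the pad back at the coordinate-map image of the unpadded end; finally
# pick a representative as the modal sequence after rotation
# canonicalization (an addition beyond simply reporting all iterations).

#' Find plasmid-species peaks in a consensus-read length histogram
#'
#' Lengths are binned with relative width `bin_width_fraction`; bins holding
#' at least `cutoff_percent` percent of all reads that are local maxima form
#' peaks, adjacent above-threshold bins merging into one peak at the mean
#' member length. `cutoff_percent` is interpreted as percent of the total
#' read count in the run (a floor on minor-species abundance), not of the
#' largest bin.
#'
#' @param consensus_lengths integer vector of consensus-read lengths.
#' @param cutoff_percent minimum peak size as percent of all reads
#'   (typically 10 for single-plasmid runs, 2 for pools).
#' @param bin_width_fraction relative histogram bin width (default 0.005).
#' @param half_width_fraction relative membership half-width around the peak
#'   center (default 0.01).
#' @return list of `peak_bin` objects (fields `peak_id`, `center_length`,
#'   `count`, `member_idx`), sorted by center length.
#' @export
find_peaks <- function(consensus_lengths, cutoff_percent = 10,
                       bin_width_fraction = 0.005,
                       half_width_fraction = 0.01) {
  stopifnot(length(consensus_lengths) >= 1)
  n <- length(consensus_lengths)
  b <- floor(log(consensus_lengths) / log1p(bin_width_fraction))
  rng <- (min(b) - 1L):(max(b) + 1L)
  counts <- tabulate(b - min(b) + 2L, nbins = length(rng))
  above <- counts >= cutoff_percent / 100 * n & counts > 0L
  if (!any(above))
    stop(condition_error("no_peaks", "no histogram bin passes the cutoff"))
  grp <- rle(above)
  gend <- cumsum(grp$lengths)
  gstart <- gend - grp$lengths + 1L
  peaks <- list()
  for (k in which(grp$values)) {
    gi <- gstart[k]:gend[k]
    # the group must contain a genuine local maximum
    mx <- gi[which.max(counts[gi])]
    left <- if (mx > 1L) counts[mx - 1L] else 0L
    right <- if (mx < length(counts)) counts[mx + 1L] else 0L
    if (counts[mx] < max(left, right)) next
    in_group <- b %in% rng[gi]
    center <- mean(consensus_lengths[in_group])
    members <- which(abs(consensus_lengths - center) <=
                       half_width_fraction * center)
    peaks <- c(peaks, list(structure(
      list(center_length = center, count = length(members),
           member_idx = members,
           half_width_fraction = half_width_fraction),
      class = "peak_bin")))
  }
  if (!length(peaks))
    stop(condition_error("no_peaks", "no local maximum passes the cutoff"))
  peaks <- peaks[order(vapply(peaks, `[[`, numeric(1), "center_length"))]
  for (i in seq_along(peaks)) peaks[[i]]$peak_id <-
    sprintf("peak_%d", round(peaks[[i]]$center_length))
  peaks
}

#' Rank candidate templates within a peak
#'
#' Descending by subread coverage, then mean subread Q, then read id (a
#' deterministic tie-break).
#'
#' @param members list of `consensus_read` objects.
#' @return the list reordered.
#' @export
rank_templates <- function(members) {
  stopifnot(length(members) >= 1)
  cov <- vapply(members, `[[`, numeric(1), "subread_count")
  q <- vapply(members, `[[`, numeric(1), "mean_subread_q")
  id <- vapply(members, `[[`, character(1), "read_id")
  members[order(-cov, -q, id)]
}

#' Select the highest-quality evidence subreads for a peak
#'
#' @param subreads_in_peak list of subreads whose parent consensus read is a
#'   peak member.
#' @param n_subreads number to keep (default 500); all are returned when
#'   fewer exist.
#' @return the top `n_subreads` subreads by mean Q, descending.
#' @export
rank_evidence <- function(subreads_in_peak, n_subreads = 500L) {
  q <- vapply(subreads_in_peak, `[[`, numeric(1), "mean_q")
  id <- vapply(subreads_in_peak, `[[`, character(1), "subread_id")
  head(subreads_in_peak[order(-q, id)], n_subreads)
}

#' Pad a circular sequence for polishing
#'
#' Appends the first half of the sequence to its end, so that alignment
#' evidence is not truncated at the arbitrary circular origin.
#'
#' @param sequence DNA string (length >= 2).
#' @return the padded string of length `n + floor(n/2)`.
#' @export
pad_circular <- function(sequence) {
  n <- nchar(sequence)
  stopifnot(n >= 2)
  paste0(sequence, substr(sequence, 1L, n %/% 2L))
}

# Phase-align evidence to the template origin. A full-length subread is one
# complete turn of the circle starting at an arbitrary phase; rotating it to
# start at the template origin makes it align contiguously over the whole
# unit, giving uniform pileup coverage (whereas splitting into half-unit
# pieces dilutes coverage near the origin between its two images in the
# padded template). The origin is located in the subread by a probe taken
# from the template start, in both orientations; when the probe cannot be
# located (it spans the subread's own seam, or the read is a partial flank)
# the evidence is split into half-unit pieces instead, which always place
# contiguously.
phase_align_evidence <- function(subreads, template_seq, unit_len,
                                 probe_len = 200L) {
  probe <- substr(template_seq, 1L, min(probe_len, max(50L, unit_len %/% 4L)))
  thr <- 0.3 * nchar(probe)
  out <- list()
  for (s in subreads) {
    n <- nchar(s$sequence)
    if (n >= 0.8 * unit_len && n >= nchar(probe) + 50L) {
      fwd <- cpp_semiglobal(probe, s$sequence, FALSE)
      rcseq <- revcomp(s$sequence)
      rev <- cpp_semiglobal(probe, rcseq, FALSE)
      if (min(fwd$dist, rev$dist) <= thr) {
        if (rev$dist < fwd$dist) {
          seq <- rcseq; qual <- rev(s$qualities); hit <- rev
        } else {
          seq <- s$sequence; qual <- s$qualities; hit <- fwd
        }
        start <- max(1L, hit$t_end - nchar(probe) + 1L)
        rot <- c(start:n, if (start > 1L) 1:(start - 1L))
        qual <- qual[rot]
        out <- c(out, list(list(sequence = rotate_seq(seq, start),
                                qualities = qual,
                                mean_q = mean_read_q(qual)$mean_q)))
        next
      }
    }
    out <- c(out, split_evidence_pieces(list(s), unit_len))
  }
  out
}

# Split evidence into contiguous pieces no longer than half the template
# unit. Any half-unit window of the circular molecule is guaranteed to map
# contiguously into the 1.5-unit padded template, whereas a full-unit
# subread whose phase is offset by more than half a unit would wrap.
split_evidence_pieces <- function(subreads, unit_len, min_piece = 50L) {
  out <- list()
  half <- unit_len / 2
  for (s in subreads) {
    n <- nchar(s$sequence)
    k <- max(1L, ceiling(n / half))
    bounds <- round(seq(0L, n, length.out = k + 1L))
    for (j in seq_len(k)) {
      from <- bounds[j] + 1L; to <- bounds[j + 1L]
      if (to - from + 1L < min_piece) next
      qual <- s$qualities[from:to]
      out <- c(out, list(list(sequence = substr(s$sequence, from, to),
                              qualities = qual,
                              mean_q = mean_read_q(qual)$mean_q)))
    }
  }
  out
}

#' Polish one template consensus read into a full-length plasmid sequence
#'
#' Pads the template circularly, runs a uniform-weight polish round followed
#' by a quality-weighted round (with homopolymer run-length voting), then
#' trims at the composed coordinate-map image of the unpadded template end.
#' The cut is refined within +/- 2 bases to the position maximizing circular
#' self-consistency (the trimmed-away pad must replicate the output start).
#' Evidence subreads are aligned in both orientations each round; full-unit
#' subreads are first rotated to the template origin so they align
#' contiguously over the whole unit (partial flanks, and subreads whose
#' origin cannot be located, are split into half-unit pieces instead).
#'
#' @param template_consensus a `consensus_read` (a peak member).
#' @param evidence_subreads subreads selected by [rank_evidence].
#' @param iteration_index 0-based index recorded in the output.
#' @param peak_id recorded in the output.
#' @return an object of class `polished_plasmid` (fields `peak_id`,
#'   `iteration_index`, `sequence`, `template_read_id`,
#'   `n_evidence_subreads`).
#' @export
polish_plasmid <- function(template_consensus, evidence_subreads,
                           iteration_index = 0L, peak_id = NA_character_) {
  if (length(evidence_subreads) < 5L)
    warning("fewer than 5 evidence subreads; polishing may be unreliable")
  unit_len <- nchar(template_consensus$sequence)
  padded <- pad_circular(template_consensus$sequence)
  pieces <- phase_align_evidence(evidence_subreads,
                                 template_consensus$sequence, unit_len)
  r1 <- polish_template(padded, pieces, weighting = "uniform",
                        both_orientations = TRUE)
  r2 <- polish_template(r1$sequence, pieces, weighting = "quality",
                        both_orientations = TRUE)
  cut <- r2$coordinate_map[r1$coordinate_map[unit_len]]
  cut <- refine_circular_cut(r2$sequence, cut)
  structure(list(peak_id = peak_id,
                 iteration_index = as.integer(iteration_index),
                 sequence = substr(r2$sequence, 1L, cut),
                 template_read_id = template_consensus$read_id,
                 n_evidence_subreads = length(evidence_subreads)),
            class = "polished_plasmid")
}

# Choose the cut position (within +/- window of `cut`) maximizing identity
# between the trimmed-away pad and the output start: after a correct cut the
# suffix must replicate the prefix, because the pad is a copy of the first
# half of the circle.
refine_circular_cut <- function(sequence, cut, window = 2L, probe = 50L) {
  n <- nchar(sequence)
  cands <- max(1L, cut - window):min(n, cut + window)
  score <- vapply(cands, function(c) {
    k <- min(probe, n - c)
    if (k < 10L) return(-1)
    a <- strsplit(substr(sequence, c + 1L, c + k), "", fixed = TRUE)[[1]]
    b <- strsplit(substr(sequence, 1L, k), "", fixed = TRUE)[[1]]
    sum(a == b)
  }, numeric(1))
  cands[which.max(score)]
}

#' Demultiplex and polish a pool of consensus reads
#'
#' Finds length peaks, and for each peak independently polishes the top
#' `iterations` ranked templates with the peak's top `n_subreads` evidence
#' subreads, then picks a representative: the modal sequence among the
#' iteration outputs after rotation canonicalization (ties resolved toward
#' the output of the highest-coverage template).
#'
#' @param consensus_reads list of `consensus_read` objects carrying their
#'   subreads, or a path to a consensus FASTA (then `subreads` must be
#'   given).
#' @param subreads optional list of subreads or path to a subread FASTQ;
#'   defaults to the subreads carried by `consensus_reads`.
#' @param iterations templates polished per peak (default 100).
#' @param n_subreads evidence subreads per peak (default 500).
#' @param cutoff_percent peak cutoff as percent of total reads (default 10;
#'   use 2 for pools).
#' @param out_dir optional output directory: writes `peak_<center>.fasta`
#'   (all iterations), `peak_<center>.rep.fasta` (representative) and a
#'   tab-separated `peaks.tsv` report.
#' @return list with `peaks`, and per peak `outputs` (all polished
#'   iterations) and `representative`.
#' @export
run_chopper <- function(consensus_reads, subreads = NULL, iterations = 100L,
                        n_subreads = 500L, cutoff_percent = 10,
                        out_dir = NULL) {
  if (is.character(consensus_reads))
    consensus_reads <- read_consensus_fasta(consensus_reads)
  if (is.character(subreads)) subreads <- read_subreads_fastq(subreads)
  if (is.null(subreads))
    subreads <- unlist(lapply(consensus_reads, `[[`, "subreads"),
                       recursive = FALSE)
  stopifnot(length(subreads) >= 1)
  lens <- vapply(consensus_reads, function(x) nchar(x$sequence), numeric(1))
  peaks <- find_peaks(lens, cutoff_percent = cutoff_percent)
  parent <- vapply(subreads, `[[`, character(1), "parent_id")

  results <- lapply(peaks, function(pk) {
    members <- rank_templates(consensus_reads[pk$member_idx])
    member_ids <- vapply(members, `[[`, character(1), "read_id")
    evidence <- rank_evidence(subreads[parent %in% member_ids], n_subreads)
    templates <- head(members, iterations)
    outputs <- lapply(seq_along(templates), function(i)
      polish_plasmid(templates[[i]], evidence, iteration_index = i - 1L,
                     peak_id = pk$peak_id))
    canon <- vapply(outputs, function(o) canonical_rotation(o$sequence),
                    character(1))
    tab <- table(canon)
    modal <- names(tab)[tab == max(tab)]
    # tie-break toward the highest-coverage template's output (templates
    # are already ranked, so the first output with a modal sequence wins)
    rep_idx <- which(canon %in% modal)[1]
    list(peak = pk, outputs = outputs,
         representative = outputs[[rep_idx]],
         modal_fraction = max(tab) / length(outputs))
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    report <- data.frame(
      peak_id = vapply(results, function(r) r$peak$peak_id, character(1)),
      center_length = vapply(results, function(r) r$peak$center_length,
                             numeric(1)),
      count = vapply(results, function(r) r$peak$count, numeric(1)),
      n_outputs = vapply(results, function(r) length(r$outputs), numeric(1)),
      modal_fraction = vapply(results, `[[`, numeric(1), "modal_fraction"))
    write.table(report, file.path(out_dir, "peaks.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (r in results) {
      seqs <- setNames(
        vapply(r$outputs, `[[`, character(1), "sequence"),
        vapply(r$outputs, function(o)
          sprintf("%s_iter%d_%s", o$peak_id, o$iteration_index,
                  o$template_read_id), character(1)))
      write_fasta(seqs, file.path(out_dir, paste0(r$peak$peak_id, ".fasta")))
      write_fasta(setNames(r$representative$sequence,
                           paste0(r$peak$peak_id, "_representative")),
                  file.path(out_dir, paste0(r$peak$peak_id, ".rep.fasta")))
    }
  }
  list(peaks = peaks, results = results)
}
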
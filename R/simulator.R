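# Truth-annotated simulation of circular plasmids and RCA concatemer reads.
#
# The simulator emulates the statistical structure of rolling-circle
# amplification data: each read is a noisy tandem concatemer of one circular
# plasmid, started at a uniform random phase on a uniform random strand, with
# per-base substitution/insertion/deletion errors and systematically boosted
# indel rates inside homopolymer runs. Emitted base qualities are constant
# and deliberately blind to the boosted (systematic) errors.

#' Construct a sequencing error model
#'
#' @param sub_rate per-base substitution probability.
#' @param ins_rate per-base insertion probability.
#' @param del_rate per-base deletion probability.
#' @param homopolymer_indel_boost multiplier (>= 1) applied to `ins_rate` and
#'   `del_rate` inside homopolymer runs of length >= `homopolymer_min_run`.
#'   Inserted bases inside such runs extend the run (same base), emulating
#'   systematic run-length miscalls.
#' @param homopolymer_min_run minimum run length for the boost to apply.
#' @param q_constant emitted Phred quality per base; default
#'   `round(-10*log10(sub_rate + ins_rate + del_rate))`. Qualities are not
#'   lowered inside boosted runs: systematic errors are quality-blind.
#' @return an object of class `error_model`.
#' @export
error_model <- function(sub_rate = 0.004, ins_rate = 0.003, del_rate = 0.003,
                        homopolymer_indel_boost = 3,
                        homopolymer_min_run = 6L,
                        q_constant = NULL) {
  total <- sub_rate + ins_rate + del_rate
  stopifnot(total < 1, homopolymer_indel_boost >= 1,
            sub_rate >= 0, ins_rate >= 0, del_rate >= 0)
  if (is.null(q_constant))
    q_constant <- if (total > 0) round(-10 * log10(total)) else 93L
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate,
                 homopolymer_indel_boost = homopolymer_indel_boost,
                 homopolymer_min_run = as.integer(homopolymer_min_run),
                 q_constant = as.integer(min(93L, max(0L, q_constant)))),
            class = "error_model")
}

#' Generate a random circular plasmid sequence
#'
#' Random bases at a target GC fraction, with optional homopolymer runs
#' embedded verbatim at fixed positions (for stress-testing systematic
#' nanopore errors on runs such as 8 Cs or 16 Gs).
#'
#' @param length plasmid length in bases (>= 1000).
#' @param gc_fraction target GC content of the random background.
#' @param homopolymer_spec list of `list(base=, len=, pos=)` placements;
#'   `pos` is the 1-based start. Runs must fit without wrapping and must not
#'   overlap each other.
#' @param seed integer seed; the sequence is deterministic given the seed.
#' @return a DNA string (the `+` strand of the circular plasmid).
#' @export
make_plasmid <- function(length, gc_fraction = 0.5,
                         homopolymer_spec = list(), seed = 1L) {
  stopifnot(length >= 1000)
  if (length(homopolymer_spec)) {
    iv <- t(vapply(homopolymer_spec, function(h) {
      stopifnot(h$len >= 1, h$base %in% c("A", "C", "G", "T"))
      if (h$pos < 1 || h$pos + h$len - 1 > length)
        stop("homopolymer run at ", h$pos, " (length ", h$len,
             ") does not fit inside the plasmid (no circular wrap)")
      c(h$pos, h$pos + h$len - 1)
    }, numeric(2)))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (nrow(iv) > 1 && any(iv[-1, 1] <= iv[-nrow(iv), 2]))
      stop("overlapping homopolymer placements")
  }
  with_seed(seed, {
    p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
           G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    bases <- sample(names(p), length, replace = TRUE, prob = p)
    for (h in homopolymer_spec)
      bases[h$pos:(h$pos + h$len - 1)] <- h$base
    paste(bases, collapse = "")
  })
}

# Positions (logical mask) inside homopolymer runs of length >= min_run.
homopolymer_mask <- function(chars, min_run) {
  r <- rle(chars)
  rep(r$lengths >= min_run, r$lengths)
}

#' Simulate one concatemer read
#'
#' The error-free template traverses the circular plasmid from a uniform
#' random phase, on a uniform random strand, for `read_length` template
#' bases; errors are then applied per the error model and constant qualities
#' emitted.
#'
#' @param plasmid DNA string (`+` strand of the circular plasmid).
#' @param read_length number of template bases traversed (>= 200).
#' @param model an [error_model].
#' @param seed optional integer seed.
#' @param read_id,plasmid_id identifiers recorded in the outputs.
#' @return `list(read =` [raw_read]`, truth = list(read_id, plasmid_id,
#'   phase, strand, n_full_repeats, true_read_length))`. `phase` is the
#'   1-based start position on the `+` strand of the plasmid.
#' @export
simulate_concatemer_read <- function(plasmid, read_length, model = error_model(),
                                     seed = NULL, read_id = "read1",
                                     plasmid_id = "plasmid1") {
  stopifnot(read_length >= 200)
  L <- nchar(plasmid)
  with_seed(seed, {
    phase <- sample.int(L, 1L)
    strand <- sample(c("+", "-"), 1L)
    idx <- ((phase - 1L + seq_len(read_length) - 1L) %% L) + 1L
    template <- paste(strsplit(plasmid, "", fixed = TRUE)[[1]][idx],
                      collapse = "")
    if (strand == "-") template <- revcomp(template)
    emitted <- apply_errors(template, model)
    truth <- list(read_id = read_id, plasmid_id = plasmid_id,
                  phase = phase, strand = strand,
                  n_full_repeats = read_length %/% L,
                  true_read_length = read_length)
    list(read = raw_read(read_id, emitted$sequence,
                         rep(model$q_constant, nchar(emitted$sequence))),
         truth = truth)
  })
}

# Apply substitution/insertion/deletion errors to a template string.
# Insertions inside boosted homopolymer runs duplicate the run base.
apply_errors <- function(template, model) {
  tc <- strsplit(template, "", fixed = TRUE)[[1]]
  n <- length(tc)
  boost <- rep(1, n)
  if (model$homopolymer_indel_boost > 1)
    boost[homopolymer_mask(tc, model$homopolymer_min_run)] <-
      model$homopolymer_indel_boost
  del_p <- pmin(0.95, model$del_rate * boost)
  ins_p <- pmin(0.95, model$ins_rate * boost)
  keep <- runif(n) >= del_p
  sub <- runif(n) < model$sub_rate & keep
  ins <- runif(n) < ins_p
  out <- tc
  if (any(sub)) {
    alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T", "A", "C", "G"),
                  nrow = 4, byrow = TRUE,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
    out[sub] <- alt[cbind(match(tc[sub], rownames(alt)),
                          sample.int(3L, sum(sub), replace = TRUE))]
  }
  ins_base <- character(n)
  if (any(ins)) {
    w <- which(ins)
    rand_b <- sample(c("A", "C", "G", "T"), length(w), replace = TRUE)
    in_run <- boost[w] > 1
    ins_base[w] <- ifelse(in_run, tc[w], rand_b)
  }
  pieces <- paste0(ifelse(keep, out, ""), ins_base)
  list(sequence = paste(pieces, collapse = ""))
}

#' Simulate a sequencing run of concatemer reads
#'
#' Reads are drawn i.i.d.: plasmid chosen by the mixture weights, read length
#' drawn from a long-tailed (log-normal) distribution whose mode can sit
#' below the concatemer molecule length, then one concatemer read simulated.
#'
#' @param plasmids named list (or named character vector) of plasmid
#'   sequences.
#' @param n_reads number of reads to simulate (>= 1).
#' @param length_distribution `list(meanlog=, sdlog=, min=)` of the
#'   log-normal read-length distribution (template bases).
#' @param model an [error_model].
#' @param weights mixture weights per plasmid (default uniform).
#' @param seed integer seed; outputs are byte-identical given the seed.
#' @param out_fastq,out_truth optional paths; when given, the FASTQ and a
#'   tab-separated truth table are written there.
#' @return `list(reads = list of raw_read, truth = data.frame, fastq =,
#'   truth_path =)`.
#' @export
simulate_run <- function(plasmids, n_reads,
                         length_distribution = list(meanlog = log(8000),
                                                    sdlog = 0.6, min = 500),
                         model = error_model(), weights = NULL,
                         seed = 1L, out_fastq = NULL, out_truth = NULL) {
  stopifnot(length(plasmids) >= 1, n_reads >= 1)
  plasmids <- as.list(plasmids)
  if (is.null(names(plasmids)) || any(!nzchar(names(plasmids))))
    names(plasmids) <- paste0("plasmid", seq_along(plasmids))
  if (is.null(weights)) weights <- rep(1, length(plasmids))
  with_seed(seed, {
    which_p <- sample.int(length(plasmids), n_reads, replace = TRUE,
                          prob = weights / sum(weights))
    lens <- pmax(length_distribution$min,
                 round(rlnorm(n_reads, length_distribution$meanlog,
                              length_distribution$sdlog)))
    reads <- vector("list", n_reads)
    truth <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      sim <- simulate_concatemer_read(
        plasmids[[which_p[i]]], lens[i], model, seed = NULL,
        read_id = sprintf("read%05d", i),
        plasmid_id = names(plasmids)[which_p[i]])
      reads[[i]] <- sim$read
      truth[[i]] <- sim$truth
    }
    truth_df <- do.call(rbind, lapply(truth, function(t)
      data.frame(t, stringsAsFactors = FALSE)))
    if (!is.null(out_fastq)) write_fastq(reads, out_fastq)
    if (!is.null(out_truth))
      write.table(truth_df, out_truth, sep = "\t", quote = FALSE,
                  row.names = FALSE)
    list(reads = reads, truth = truth_df,
         fastq = out_fastq, truth_path = out_truth)
  })
}
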
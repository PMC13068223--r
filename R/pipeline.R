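# End-to-end pipeline: simulate (optional) -> split/consensus -> chopper ->
# evaluate, with per-stage read-attrition accounting. Skip accounting is the
# main debugging surface of this method, so every stage reports reads in,
# reads skipped by reason, and reads out.

#' Build consensus reads for a whole run
#'
#' Applies [make_consensus_read] to every read and tallies skip reasons.
#'
#' @param reads list of [raw_read] objects (or a FASTQ path).
#' @param config a [consensus_config].
#' @param verbose print per-stage attrition counts.
#' @return `list(consensus = list of consensus_read, skips = named counts,
#'   skip_reasons = per-read reasons)`.
#' @export
consensus_run <- function(reads, config = consensus_config(),
                          verbose = FALSE) {
  if (is.character(reads)) reads <- read_fastq(reads)
  res <- lapply(reads, make_consensus_read, config = config)
  is_skip <- vapply(res, inherits, logical(1), "consensus_skip")
  reasons <- vapply(res[is_skip], `[[`, character(1), "reason")
  skips <- table(factor(reasons, levels = c("too_short", "anchor_hits",
                                            "length_inconsistent",
                                            "polish_failed")))
  if (verbose)
    message(sprintf(
      "consensus: %d reads in, %d consensus out (skipped: %s)",
      length(reads), sum(!is_skip),
      paste(names(skips), as.integer(skips), sep = "=", collapse = ", ")))
  list(consensus = res[!is_skip], skips = c(skips),
       skip_reasons = reasons)
}

#' Run the full pipeline
#'
#' Either simulates a run (when `plasmids` is given) or reads an input
#' FASTQ, builds consensus reads, demultiplexes and polishes with the
#' chopper stage, and (when references are available) evaluates identities
#' and full-length error-free fractions per peak.
#'
#' @param fastq input FASTQ path (ignored when `plasmids` is given).
#' @param plasmids named list of plasmid sequences to simulate from.
#' @param n_reads,length_distribution,model,weights simulation parameters,
#'   see [simulate_run].
#' @param references named list of reference sequences for evaluation;
#'   defaults to `plasmids` when simulating.
#' @param iterations,n_subreads,cutoff_percent chopper parameters.
#' @param config consensus-calling parameters.
#' @param out_dir optional directory for all file outputs.
#' @param seed integer seed controlling every stochastic step.
#' @param verbose print per-stage progress.
#' @return list with `truth` (when simulated), `attrition`, `chopper`
#'   (peaks and polished outputs) and `evaluation` (per-peak summary, when
#'   references are available).
#' @export
run_pipeline <- function(fastq = NULL, plasmids = NULL, n_reads = 300L,
                         length_distribution = list(meanlog = log(8000),
                                                    sdlog = 0.6, min = 500),
                         model = error_model(), weights = NULL,
                         references = NULL,
                         iterations = 20L, n_subreads = 50L,
                         cutoff_percent = 10, config = consensus_config(),
                         out_dir = NULL, seed = 1L, verbose = FALSE) {
  truth <- NULL
  if (!is.null(plasmids)) {
    sim <- simulate_run(plasmids, n_reads, length_distribution, model,
                        weights, seed = derive_seed(seed, 1L),
                        out_fastq = if (!is.null(out_dir)) {
                          dir.create(out_dir, showWarnings = FALSE,
                                     recursive = TRUE)
                          file.path(out_dir, "simulated.fastq")
                        },
                        out_truth = if (!is.null(out_dir))
                          file.path(out_dir, "truth.tsv"))
    reads <- sim$reads
    truth <- sim$truth
    if (is.null(references)) references <- plasmids
  } else {
    if (is.null(fastq)) stop("either 'fastq' or 'plasmids' must be given")
    if (!file.exists(fastq)) stop("input FASTQ not found: ", fastq)
    reads <- read_fastq(fastq)
  }
  cr <- consensus_run(reads, config, verbose = verbose)
  if (!length(cr$consensus))
    stop("consensus stage produced no reads (all skipped)")
  if (!is.null(out_dir)) {
    write_consensus_fasta(cr$consensus,
                          file.path(out_dir, "consensus.fasta"))
    write_subreads_fastq(
      unlist(lapply(cr$consensus, `[[`, "subreads"), recursive = FALSE),
      file.path(out_dir, "subreads.fastq"))
  }
  ch <- run_chopper(cr$consensus, iterations = iterations,
                    n_subreads = n_subreads,
                    cutoff_percent = cutoff_percent,
                    out_dir = if (!is.null(out_dir))
                      file.path(out_dir, "chopper"))
  if (verbose)
    message(sprintf("chopper: %d peaks (%s)", length(ch$peaks),
                    paste(vapply(ch$peaks, function(p)
                      sprintf("%s n=%d", p$peak_id, p$count),
                      character(1)), collapse = "; ")))
  evaluation <- NULL
  if (!is.null(references)) {
    evaluation <- lapply(ch$results, function(r) {
      # match the peak to the closest reference by length
      rl <- vapply(references, nchar, numeric(1))
      ref_id <- names(references)[which.min(abs(rl - r$peak$center_length))]
      ref <- references[[ref_id]]
      ff <- vapply(r$outputs, function(o)
        is_full_length_error_free(o$sequence, ref), logical(1))
      rep_ff <- is_full_length_error_free(r$representative$sequence, ref)
      list(peak_id = r$peak$peak_id, reference = ref_id,
           n_outputs = length(ff),
           error_free_fraction = mean(ff),
           representative_error_free = rep_ff)
    })
    if (verbose) for (e in evaluation)
      message(sprintf(
        "evaluate: %s vs %s: %.0f%% of %d outputs full-length error-free; representative %s",
        e$peak_id, e$reference, 100 * e$error_free_fraction, e$n_outputs,
        if (e$representative_error_free) "error-free" else "has errors"))
  }
  list(truth = truth, attrition = cr$skips, n_consensus = length(cr$consensus),
       chopper = ch, evaluation = evaluation)
}
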
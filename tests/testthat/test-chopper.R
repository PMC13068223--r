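test_that("peak finding separates well-spaced length clusters", {
  set.seed(5)
  lens <- c(round(rnorm(500, 5542, 5542 * 0.003)),
            round(rnorm(400, 14874, 14874 * 0.003)),
            round(runif(50, 2000, 20000)))
  peaks <- find_peaks(lens, cutoff_percent = 2)
  expect_length(peaks, 2L)
  centers <- vapply(peaks, `[[`, numeric(1), "center_length")
  expect_lt(abs(centers[1] - 5542) / 5542, 0.005)
  expect_lt(abs(centers[2] - 14874) / 14874, 0.005)
})

test_that("a single tight cluster yields one peak holding nearly all members", {
  set.seed(6)
  lens <- round(rnorm(300, 6000, 10))
  peaks <- find_peaks(lens, cutoff_percent = 10)
  expect_length(peaks, 1L)
  expect_gte(peaks[[1]]$count, 0.99 * 300)
})

test_that("identical lengths collapse to one full peak", {
  peaks <- find_peaks(rep(4000L, 25), cutoff_percent = 10)
  expect_length(peaks, 1L)
  expect_equal(peaks[[1]]$count, 25L)
  expect_equal(peaks[[1]]$center_length, 4000)
})

test_that("no bin above cutoff raises no_peaks", {
  expect_error(find_peaks(seq(1000, 9000, by = 97), cutoff_percent = 10),
               class = "no_peaks")
})

test_that("clusters 0.5% apart merge while 2% apart stay separate", {
  set.seed(8)
  near <- c(round(rnorm(200, 6000, 5)), round(rnorm(200, 6030, 5)))
  expect_length(find_peaks(near, cutoff_percent = 2), 1L)
  far <- c(round(rnorm(200, 6000, 5)), round(rnorm(200, 6120, 5)))
  peaks <- find_peaks(far, cutoff_percent = 2)
  expect_length(peaks, 2L)
  expect_equal(length(intersect(peaks[[1]]$member_idx,
                                peaks[[2]]$member_idx)), 0L)
})

test_that("template ranking is by coverage, then Q, then id", {
  mk <- function(id, cov, q)
    structure(list(read_id = id, sequence = "ACGT", subread_count = cov,
                   mean_subread_q = q, subreads = NULL),
              class = "consensus_read")
  m <- list(mk("a", 3, 12), mk("b", 5, 9), mk("c", 5, 11))
  r <- rank_templates(m)
  expect_equal(vapply(r, `[[`, character(1), "read_id"), c("c", "b", "a"))
  expect_equal(rank_templates(m[2])[[1]]$read_id, "b")
  ties <- list(mk("z", 5, 10), mk("y", 5, 10))
  expect_equal(vapply(rank_templates(ties), `[[`, character(1), "read_id"),
               c("y", "z"))
})

test_that("evidence ranking keeps the top n by mean Q", {
  mk <- function(i, q) list(parent_id = "r", subread_id = sprintf("r_%d", i),
                            index = i, sequence = "ACGT",
                            qualities = rep(q, 4), is_partial = FALSE,
                            mean_q = q)
  set.seed(9)
  qs <- sample(5:40, 30, replace = TRUE)
  subs <- lapply(seq_along(qs), function(i) mk(i, qs[i]))
  top <- rank_evidence(subs, 10)
  expect_length(top, 10L)
  expect_equal(vapply(top, `[[`, numeric(1), "mean_q"),
               sort(qs, decreasing = TRUE)[1:10])
  expect_length(rank_evidence(subs, 500), 30L)
})

test_that("circular padding appends the first half", {
  expect_equal(pad_circular("ABCDEFGH"), "ABCDEFGHABCD")
  expect_equal(nchar(pad_circular(strrep("A", 9))), 9 + 4)
  set.seed(10)
  s <- paste(sample(c("A", "C", "G", "T"), 101, replace = TRUE),
             collapse = "")
  expect_equal(substr(pad_circular(s), 1, 101), s)
})

test_that("polishing a zero-error peak returns the template exactly", {
  pl <- fixture_plasmid(1500, seed = 31)
  sim <- simulate_run(list(p = pl), 12,
                      list(meanlog = log(5000), sdlog = 0.2, min = 2000),
                      model = zero_error_model(), seed = 17)
  cr <- consensus_run(sim$reads)
  subs <- unlist(lapply(cr$consensus, `[[`, "subreads"), recursive = FALSE)
  tmpl <- rank_templates(cr$consensus)[[1]]
  out <- polish_plasmid(tmpl, rank_evidence(subs, 50))
  # padding neutrality: pad fully trimmed, template returned bit-exact
  expect_equal(out$sequence, tmpl$sequence)
  expect_true(is_rotation_of(out$sequence, pl))
})

test_that("polished outputs for one noisy peak are rotations of the truth", {
  pl <- fixture_plasmid(2000, seed = 32)
  sim <- simulate_run(list(p = pl), 40,
                      list(meanlog = log(7000), sdlog = 0.3, min = 2500),
                      model = one_percent_model(), seed = 23)
  cr <- consensus_run(sim$reads)
  ch <- run_chopper(cr$consensus, iterations = 4, n_subreads = 50,
                    cutoff_percent = 10)
  expect_length(ch$peaks, 1L)
  outs <- ch$results[[1]]$outputs
  expect_length(outs, 4L)
  canon <- vapply(outs, function(o) canonical_rotation(o$sequence),
                  character(1))
  # rotation closure: all iterations agree up to rotation/strand
  expect_length(unique(canon), 1L)
  expect_true(is_rotation_of(ch$results[[1]]$representative$sequence, pl))
})

test_that("run_chopper writes per-peak outputs and a report", {
  pl <- fixture_plasmid(1500, seed = 33)
  sim <- simulate_run(list(p = pl), 15,
                      list(meanlog = log(5000), sdlog = 0.2, min = 2000),
                      model = zero_error_model(), seed = 3)
  cr <- consensus_run(sim$reads)
  out_dir <- withr::local_tempdir()
  ch <- run_chopper(cr$consensus, iterations = 1, n_subreads = 20,
                    cutoff_percent = 10, out_dir = out_dir)
  expect_length(ch$results[[1]]$outputs, 1L)
  pk <- ch$peaks[[1]]$peak_id
  expect_true(file.exists(file.path(out_dir, paste0(pk, ".fasta"))))
  expect_true(file.exists(file.path(out_dir, paste0(pk, ".rep.fasta"))))
  rep <- read.delim(file.path(out_dir, "peaks.tsv"))
  expect_equal(nrow(rep), 1L)
  expect_equal(rep$count, ch$peaks[[1]]$count)
})

test_that("consensus/subread file handoff feeds run_chopper", {
  pl <- fixture_plasmid(1500, seed = 34)
  sim <- simulate_run(list(p = pl), 15,
                      list(meanlog = log(5000), sdlog = 0.2, min = 2000),
                      model = zero_error_model(), seed = 4)
  cr <- consensus_run(sim$reads)
  fa <- withr::local_tempfile(fileext = ".fasta")
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_consensus_fasta(cr$consensus, fa)
  write_subreads_fastq(unlist(lapply(cr$consensus, `[[`, "subreads"),
                              recursive = FALSE), fq)
  ch <- run_chopper(fa, fq, iterations = 1, n_subreads = 20,
                    cutoff_percent = 10)
  expect_true(is_rotation_of(ch$results[[1]]$representative$sequence, pl))
})

test_that("polishing never lowers the error-free fraction under balanced run noise", {
  # symmetric homopolymer noise calibrated so about half the evidence
  # misreads the 16-base run: the pooled run-length median still recovers
  # the true length, so polishing rescues templates with wrong runs and
  # the polished error-free fraction is at least the template fraction
  runs <- list(list(base = "G", len = 16L, pos = 800L))
  pl <- make_plasmid(2500, homopolymer_spec = runs, seed = 35)
  m <- error_model(0.004, 0.003, 0.003, homopolymer_indel_boost = 7)
  sim <- simulate_run(list(p = pl), 40,
                      list(meanlog = log(8000), sdlog = 0.4, min = 2000),
                      model = m, seed = 45)
  cr <- consensus_run(sim$reads)
  ch <- run_chopper(cr$consensus, iterations = 8, n_subreads = 50,
                    cutoff_percent = 10)
  r <- ch$results[[1]]
  out_ff <- vapply(r$outputs, function(o)
    is_full_length_error_free(o$sequence, pl), logical(1))
  cons_ids <- vapply(cr$consensus, `[[`, character(1), "read_id")
  tmpl_ff <- vapply(r$outputs, function(o)
    is_full_length_error_free(
      cr$consensus[[which(cons_ids == o$template_read_id)]]$sequence, pl),
    logical(1))
  expect_gte(mean(out_ff), mean(tmpl_ff))
})
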
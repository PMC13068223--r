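test_that("make_plasmid embeds requested homopolymer runs verbatim and is deterministic", {
  runs <- list(list(base = "C", len = 8L, pos = 1000L),
               list(base = "G", len = 16L, pos = 1100L))
  p1 <- make_plasmid(5000, homopolymer_spec = runs, seed = 7)
  p2 <- make_plasmid(5000, homopolymer_spec = runs, seed = 7)
  expect_identical(p1, p2)
  expect_equal(substr(p1, 1000, 1007), strrep("C", 8))
  expect_equal(substr(p1, 1100, 1115), strrep("G", 16))
  expect_false(identical(p1, make_plasmid(5000, homopolymer_spec = runs,
                                          seed = 8)))
})

test_that("make_plasmid rejects runs that do not fit or overlap", {
  expect_error(make_plasmid(5000, homopolymer_spec =
    list(list(base = "G", len = 16L, pos = 4996L))), "fit")
  expect_error(make_plasmid(5000, homopolymer_spec =
    list(list(base = "C", len = 8L, pos = 1000L),
         list(base = "G", len = 16L, pos = 1004L))), "overlap")
})

test_that("make_plasmid background tracks the requested GC fraction", {
  p <- make_plasmid(20000, gc_fraction = 0.3, seed = 5)
  gc <- mean(strsplit(p, "", fixed = TRUE)[[1]] %in% c("G", "C"))
  expect_equal(gc, 0.3, tolerance = 0.03)
})

test_that("zero-error concatemer reads are exact circular substrings", {
  pl <- fixture_plasmid(1000, seed = 3)
  doubled <- paste0(pl, pl, pl, pl, pl)
  for (seed in 1:5) {
    sim <- simulate_concatemer_read(pl, 3500, zero_error_model(), seed = seed)
    expect_equal(nchar(sim$read$sequence), 3500)
    expect_equal(sim$truth$n_full_repeats, 3L)
    s <- sim$read$sequence
    if (sim$truth$strand == "-") s <- revcomp(s)
    expect_true(grepl(s, doubled, fixed = TRUE))
    # phase is recorded on the + strand
    expect_equal(substr(doubled, sim$truth$phase, sim$truth$phase + 9),
                 substr(s, 1, 10))
  }
})

test_that("read of 1.5 units records one full repeat", {
  pl <- fixture_plasmid(1000, seed = 3)
  sim <- simulate_concatemer_read(pl, 1500, zero_error_model(), seed = 1)
  expect_equal(sim$truth$n_full_repeats, 1L)
})

test_that("substitution errors match the binomial expectation", {
  pl <- fixture_plasmid(2000, seed = 9)
  m <- error_model(0.01, 0, 0, homopolymer_indel_boost = 1)
  dists <- vapply(1:20, function(s) {
    sim <- simulate_concatemer_read(pl, 3500, m, seed = s)
    r <- sim$read$sequence
    if (sim$truth$strand == "-") r <- revcomp(r)
    tmpl <- substr(strrep(rotate_seq(pl, sim$truth$phase), 2L), 1, 3500)
    concatemeR:::cpp_global(r, tmpl)$dist
  }, numeric(1))
  # each read: Binomial(3500, 0.01); mean over 20 reads within 3 sigma
  expect_equal(mean(dists), 35, tolerance = 3 * sqrt(35 * 0.99 / 20) / 35)
})

test_that("per-base error rates converge to the model rates", {
  pl <- fixture_plasmid(2000, seed = 10)
  m <- error_model(0.02, 0, 0, homopolymer_indel_boost = 1)
  n <- 30
  mm <- vapply(1:n, function(s) {
    sim <- simulate_concatemer_read(pl, 2000, m, seed = 100 + s)
    r <- sim$read$sequence
    if (sim$truth$strand == "-") r <- revcomp(r)
    tmpl <- rotate_seq(pl, sim$truth$phase)
    concatemeR:::cpp_global(r, tmpl)$dist
  }, numeric(1))
  p_hat <- sum(mm) / (n * 2000)
  se <- sqrt(0.02 * 0.98 / (n * 2000))
  expect_lt(abs(p_hat - 0.02), 3 * se)
})

test_that("homopolymer runs accumulate boosted indel rates", {
  runs <- list(list(base = "G", len = 16L, pos = 500L))
  pl <- make_plasmid(2000, homopolymer_spec = runs, seed = 4)
  m <- error_model(0, 0.003, 0.003, homopolymer_indel_boost = 6)
  in_run <- 0; total_run_bases <- 0
  out_run <- 0; total_out_bases <- 0
  for (s in 1:60) {
    sim <- simulate_concatemer_read(pl, 2000, m, seed = 200 + s)
    r <- sim$read$sequence
    if (sim$truth$strand == "-") r <- revcomp(r)
    tmpl <- rotate_seq(pl, sim$truth$phase)
    a <- concatemeR:::cpp_semiglobal(r, tmpl)
    d <- concatemeR:::decode_ops(a$ops, a$t_start)
    run_start <- ((500 - sim$truth$phase) %% 2000) + 1
    # include one flank on each side: equivalent-cost alignments may attach
    # run indels just outside the run
    run_pos <- ((run_start + (-1):16 - 1) %% 2000) + 1
    indel <- d$op %in% c("I", "D")
    inr <- d$tpos %in% run_pos
    in_run <- in_run + sum(indel & inr)
    out_run <- out_run + sum(indel & !inr)
    total_run_bases <- total_run_bases + 18
    total_out_bases <- total_out_bases + 2000 - 18
  }
  rate_in <- in_run / total_run_bases
  rate_out <- out_run / total_out_bases
  # boosted runs must show at least boost/2 = 3x the background indel rate
  expect_gt(rate_in, 3 * rate_out)
})

test_that("simulate_run is deterministic and writes matching files", {
  pl <- fixture_plasmid(1200, seed = 2)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  t1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  t2 <- withr::local_tempfile(fileext = ".tsv")
  r1 <- simulate_run(list(a = pl), 50, list(meanlog = log(3000), sdlog = 0.4,
                                            min = 500),
                     seed = 11, out_fastq = f1, out_truth = t1)
  r2 <- simulate_run(list(a = pl), 50, list(meanlog = log(3000), sdlog = 0.4,
                                            min = 500),
                     seed = 11, out_fastq = f2, out_truth = t2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(t1), readLines(t2))
  expect_length(r1$reads, 50)
  expect_equal(nrow(r1$truth), 50)
  tt <- read.delim(t1)
  expect_equal(names(tt), c("read_id", "plasmid_id", "phase", "strand",
                            "n_full_repeats", "true_read_length"))
})

test_that("mixture weights give binomially consistent per-plasmid counts", {
  p1 <- fixture_plasmid(1000, seed = 1)
  p2 <- fixture_plasmid(1000, seed = 2)
  r <- simulate_run(list(a = p1, b = p2), 2000,
                    list(meanlog = log(1500), sdlog = 0.2, min = 500),
                    model = zero_error_model(), weights = c(0.5, 0.5),
                    seed = 5)
  counts <- table(r$truth$plasmid_id)
  sigma <- sqrt(2000 * 0.25)
  expect_lt(abs(counts[["a"]] - 1000), 3 * sigma)
})
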
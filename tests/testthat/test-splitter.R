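test_that("extract_anchor slices the expected window", {
  r <- raw_read("r1", strrep("ACGT", 250), rep(30, 1000))
  a <- extract_anchor(r, offset = 250, anchor_length = 200)
  expect_equal(a$sequence, substr(r$sequence, 251, 450))
  expect_equal(a$source_start, 251L)
  b <- extract_anchor(raw_read("r2", "ACGTACGT", rep(30, 8)),
                      offset = 0, anchor_length = 4)
  expect_equal(b$sequence, "ACGT")
})

test_that("too-short reads raise a read_too_short condition", {
  r <- raw_read("short", strrep("A", 300), rep(30, 300))
  expect_error(extract_anchor(r), class = "read_too_short")
})

test_that("anchor hits on zero-error concatemers match exact string search", {
  pl <- fixture_plasmid(1000, seed = 7)
  read <- exact_concatemer(pl, 3.5, phase = 101)
  a <- extract_anchor(read)
  b <- locate_anchor(read, a)
  # independent oracle: exact fixed-string search
  oracle <- gregexpr(a$sequence, read$sequence, fixed = TRUE)[[1]]
  expect_true(b$usable)
  expect_equal(as.integer(b$hit_positions), as.integer(oracle))
  expect_equal(as.integer(b$hit_positions), c(251L, 1251L, 2251L, 3251L))
  expect_equal(b$repeat_length_estimate, 1000)
})

test_that("anchor hits tolerate ~5% errors at each repeat", {
  pl <- fixture_plasmid(1000, seed = 8)
  m <- error_model(0.05, 0, 0, homopolymer_indel_boost = 1)
  for (s in 1:5) {
    sim <- simulate_concatemer_read(pl, 3500, m, seed = s)
    a <- extract_anchor(sim$read)
    b <- locate_anchor(sim$read, a)
    expect_true(b$usable)
    ref <- exact_concatemer(pl, 3.5, phase = sim$truth$phase,
                            strand = sim$truth$strand)
    b0 <- locate_anchor(ref, extract_anchor(ref))
    expect_equal(length(b$hit_positions), length(b0$hit_positions))
    expect_true(all(abs(b$hit_positions - b0$hit_positions) <= 5))
  }
})

test_that("hit positions are strand-invariant for the same molecule", {
  # the anchor comes from the read itself, so the strand the molecule was
  # sequenced on cannot change the spacing of the hits
  pl <- fixture_plasmid(1200, seed = 9)
  for (phase in c(1, 500, 900)) {
    fw <- exact_concatemer(pl, 3.2, phase = phase, strand = "+")
    rv <- exact_concatemer(pl, 3.2, phase = phase, strand = "-")
    bf <- locate_anchor(fw, extract_anchor(fw))
    br <- locate_anchor(rv, extract_anchor(rv))
    expect_equal(bf$repeat_length_estimate, 1200)
    expect_equal(br$repeat_length_estimate, 1200)
  }
})

test_that("reads without a second repeat are flagged unusable", {
  pl <- fixture_plasmid(2000, seed = 10)
  read <- exact_concatemer(pl, 0.6)  # 1200 bases < offset + anchor + unit
  b <- locate_anchor(read, extract_anchor(read))
  expect_false(b$usable)
})

test_that("subread slicing follows the boundary arithmetic", {
  pl <- fixture_plasmid(1000, seed = 11)
  read <- exact_concatemer(pl, 3.5, phase = 1)
  b <- locate_anchor(read, extract_anchor(read))
  subs <- split_into_subreads(read, b)
  full <- Filter(function(s) !s$is_partial, subs)
  part <- Filter(function(s) s$is_partial, subs)
  h <- b$hit_positions
  # full subreads tile the read between consecutive hits
  expect_equal(length(full), length(h) - 1L)
  expect_equal(paste(vapply(full, `[[`, character(1), "sequence"),
                     collapse = ""),
               substr(read$sequence, h[1], h[length(h)] - 1L))
  # prefix flank is 250/1000 = 25% of the unit: kept as partial
  expect_equal(part[[1]]$sequence, substr(read$sequence, 1, h[1] - 1L))
  # qualities sliced identically
  expect_equal(full[[1]]$qualities,
               read$qualities[h[1]:(h[2] - 1L)])
  # ids: full <parent>_<i>, partial suffixed _p
  expect_true(all(grepl("_p$", vapply(part, `[[`, character(1),
                                      "subread_id"))))
  expect_false(any(grepl("_p$", vapply(full, `[[`, character(1),
                                       "subread_id"))))
})

test_that("short terminal flanks are dropped at the 20% threshold", {
  pl <- fixture_plasmid(2000, seed = 12)
  # phase 1: prefix flank is 250 bases = 12.5% of unit -> dropped
  read <- exact_concatemer(pl, 2.5, phase = 1)
  b <- locate_anchor(read, extract_anchor(read))
  subs <- split_into_subreads(read, b)
  part <- Filter(function(s) s$is_partial, subs)
  lens <- vapply(part, function(s) nchar(s$sequence), numeric(1))
  expect_true(all(lens >= 0.2 * b$repeat_length_estimate))
})

test_that("length consistency separates clean from faulty splits", {
  mk <- function(lens, partial = FALSE) lapply(seq_along(lens), function(i)
    list(parent_id = "r", subread_id = paste0("r_", i), index = i,
         sequence = strrep("A", lens[i]), qualities = rep(30L, lens[i]),
         is_partial = partial, mean_q = 30))
  expect_true(length_consistency_check(mk(c(1000, 1004, 996))))
  expect_false(length_consistency_check(mk(c(1000, 1800, 400))))
  expect_true(length_consistency_check(mk(1000)))
  # partials never participate
  subs <- c(mk(c(1000, 1002)), mk(300, partial = TRUE))
  expect_true(length_consistency_check(subs))
})

test_that("an internal tandem duplication trips the length guard", {
  # unit with an internal 600-base tandem duplication covering the anchor
  # window: the anchor recurs at sub-unit spacing, so subread lengths
  # alternate (600 / 1400) and the read must be rejected
  bg <- fixture_plasmid(2000, seed = 13)
  dup <- substr(bg, 1201, 1800)
  pl <- paste0(substr(bg, 1, 200), dup, dup, substr(bg, 401, 1000))
  expect_equal(nchar(pl), 2000L)
  read <- exact_concatemer(pl, 2.6, phase = 1)
  a <- extract_anchor(read)          # anchor 251..450 inside the first copy
  b <- locate_anchor(read, a)
  expect_true(b$usable)
  subs <- split_into_subreads(read, b)
  expect_false(length_consistency_check(subs))
})
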
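# Thin R-side helpers over the Rcpp edit-alignment core.

# Decode an edit-script string (ops over M/X/I/D) into per-op target and
# query positions. For target-consuming ops (M/X/D) `tpos` is the 1-based
# target position of the op; for insertions (I) it is the position of the
# last consumed target base (the position the insertion follows; 0 if the
# insertion precedes the aligned stretch). `qpos` is the 1-based query
# position for query-consuming ops (M/X/I).
decode_ops <- function(ops, t_start) {
  v <- strsplit(ops, "", fixed = TRUE)[[1]]
  tcon <- v != "I"
  qcon <- v != "D"
  list(op = v,
       tpos = t_start - 1L + cumsum(tcon),
       qpos = cumsum(qcon))
}

# Align `query` fully against a local stretch of `target`, optionally trying
# both orientations (the better one wins). Returns the cpp_semiglobal result
# plus `oriented_seq` and `rc` (whether the reverse complement was used).
align_evidence <- function(query, target, both_orientations = FALSE,
                           clear_hit_fraction = 0.12) {
  a <- cpp_semiglobal(query, target, TRUE)
  rc <- FALSE
  if (both_orientations && a$dist > clear_hit_fraction * nchar(query)) {
    qrc <- revcomp(query)
    b <- cpp_semiglobal(qrc, target, TRUE)
    if (b$dist < a$dist) { a <- b; rc <- TRUE; query <- qrc }
  }
  a$oriented_seq <- query
  a$rc <- rc
  a
}
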
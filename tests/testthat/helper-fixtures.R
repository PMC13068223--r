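# Shared fixtures built in code: small plasmids, error models, and a helper
# producing a zero-error concatemer read with known phase/strand.

fixture_plasmid <- function(len = 1000L, seed = 7L, runs = list()) {
  make_plasmid(len, gc_fraction = 0.5, homopolymer_spec = runs, seed = seed)
}

zero_error_model <- function(q = 30L)
  error_model(0, 0, 0, homopolymer_indel_boost = 1, q_constant = q)

one_percent_model <- function(boost = 1)
  error_model(0.004, 0.003, 0.003, homopolymer_indel_boost = boost)

# exact concatemer read: `reps` turns of the plasmid starting at `phase`
exact_concatemer <- function(plasmid, reps, phase = 1L, strand = "+",
                             q = 30L, read_id = "exact1") {
  L <- nchar(plasmid)
  n <- round(reps * L)
  idx <- ((phase - 1L + seq_len(n) - 1L) %% L) + 1L
  s <- paste(strsplit(plasmid, "", fixed = TRUE)[[1]][idx], collapse = "")
  if (strand == "-") s <- revcomp(s)
  raw_read(read_id, s, rep(q, n))
}

as_evidence <- function(seqs, q = 20L) {
  lapply(seq_along(seqs), function(i)
    list(sequence = seqs[[i]], qualities = rep(q, nchar(seqs[[i]])),
         mean_q = q))
}
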
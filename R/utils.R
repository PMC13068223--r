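# Small shared helpers: DNA string manipulation, seeded RNG scoping,
# condition constructors.

#' Reverse complement of a DNA string
#'
#' Operates on plain character strings over the alphabet A/C/G/T/N.
#'
#' @param x a single DNA string.
#' @return the reverse complement as a character string.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

#' Rotate a circular sequence
#'
#' @param x a DNA string representing one full turn of a circular molecule.
#' @param start 1-based position that becomes the first base.
#' @return the rotated string.
#' @export
rotate_seq <- function(x, start) {
  n <- nchar(x)
  start <- ((start - 1L) %% n) + 1L
  if (start == 1L) return(x)
  paste0(substr(x, start, n), substr(x, 1L, start - 1L))
}

#' Canonical form of a circular double-stranded sequence
#'
#' The lexicographically minimal rotation over both strands. Two sequences
#' represent the same circular molecule iff their canonical forms are equal.
#'
#' @param x a DNA string.
#' @return the canonical rotation as a character string.
#' @export
canonical_rotation <- function(x) {
  fwd <- rotate_seq(x, cpp_min_rotation(x))
  rcx <- revcomp(x)
  rev <- rotate_seq(rcx, cpp_min_rotation(rcx))
  if (fwd <= rev) fwd else rev
}

#' Test circular equality of two sequences
#'
#' @param a,b DNA strings.
#' @return TRUE iff `a` is a rotation of `b` on either strand.
#' @export
is_rotation_of <- function(a, b) {
  nchar(a) == nchar(b) && canonical_rotation(a) == canonical_rotation(b)
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a stream-specific 32-bit seed from a master seed.
derive_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(stream) * 7919L
}

condition_error <- function(class, msg, call = sys.call(-1)) {
  structure(class = c(class, "error", "condition"),
            list(message = msg, call = call))
}
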
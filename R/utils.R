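# Internal helpers shared across stages.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N and IUPAC codes).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Derive a reproducible child seed from a root seed and a label
#'
#' Each randomized stage draws from its own stream keyed by a stable label,
#' so adding a stage never perturbs the draws of another.
#'
#' @param seed integer root seed.
#' @param label character stage label.
#' @return an integer seed in `[1, 2^31 - 19)`.
#' @export
child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483629 + 1)
}

# Evaluate expr under a temporary RNG seed, restoring RNG state afterwards.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

# Width of the union of 0-based half-open intervals, clipped to [0, limit).
interval_union_width <- function(starts, ends, limit = NULL) {
  stopifnot(length(starts) == length(ends))
  if (length(starts) == 0L) return(0L)
  if (!is.null(limit)) {
    starts <- pmax(starts, 0)
    ends <- pmin(ends, limit)
    keep <- ends > starts
    starts <- starts[keep]; ends <- ends[keep]
    if (length(starts) == 0L) return(0L)
  }
  r <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
  sum(IRanges::width(r))
}

# Random DNA sequence of length n (uniform over A/C/G/T).
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Extract [start, end) from a circular sequence, 0-based; end may exceed
# nchar(x) to indicate wrap-around.
circ_substr <- function(x, start, end) {
  n <- nchar(x)
  stopifnot(end > start, end - start <= n)
  start <- start %% n
  stop_at <- start + (end - start)
  if (stop_at <= n) {
    substr(x, start + 1L, stop_at)
  } else {
    paste0(substr(x, start + 1L, n), substr(x, 1L, stop_at - n))
  }
}

# Index (0-based) of the lexicographically least rotation of a string
# (Booth's algorithm, linear time).
least_rotation_index <- function(s) {
  n <- nchar(s)
  if (n <= 1L) return(0L)
  x <- utf8ToInt(paste0(s, s))
  f <- rep(-1L, 2L * n)
  k <- 0L
  for (j in seq.int(1L, 2L * n - 1L)) { # 0-based j
    sj <- x[j + 1L]
    i <- f[j - k] # f[(j - k - 1) + 1]
    while (i != -1L && sj != x[k + i + 2L]) {
      if (sj < x[k + i + 2L]) k <- j - i - 1L
      i <- f[i + 1L]
    }
    if (sj != x[k + i + 2L]) {
      if (sj < x[k + 1L]) k <- j
      f[j - k + 1L] <- -1L
    } else {
      f[j - k + 1L] <- i + 1L
    }
  }
  k
}

# Canonical form of a circular DNA sequence: minimal rotation over both
# strands (strand whose minimal rotation is lexicographically smaller wins).
canonical_rotation <- function(s) {
  fwd <- circ_substr(paste0(s, s), least_rotation_index(s),
                     least_rotation_index(s) + nchar(s))
  rc <- revcomp(s)
  rev_rot <- circ_substr(paste0(rc, rc), least_rotation_index(rc),
                         least_rotation_index(rc) + nchar(rc))
  if (rev_rot < fwd) rev_rot else fwd
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(what, " contains characters outside {A,C,G,T,N}", call. = FALSE)
  }
  if (any(!nzchar(x))) stop(what, " must be non-empty", call. = FALSE)
  invisible(x)
}
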
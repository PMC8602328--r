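# Shared fixtures and independent oracles.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Exactly uniform toy background: one mono-residue window per standard
# residue, so every column has frequency 1/20 for every residue.
uniform_background <- function(width) {
  build_background(sequence_set(vapply(AA, function(a) strrep(a, width), "")))
}

# Independent brute-force binomial upper tail: explicit term-by-term
# summation of C(n,i) p^i (1-p)^(n-i), in log space per term.
brute_binom_tail <- function(k, n, p0) {
  if (k <= 0) return(1)
  if (p0 == 0) return(0)
  if (p0 == 1) return(1)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p0) + (n - i) * log1p(-p0)))
}

# Independent brute-force enumeration of all width-w padded subsequence
# windows of a protein, via substring on a padded string.
brute_subwindows <- function(protein, width) {
  h <- (width - 1) / 2
  padded <- paste0(strrep("-", h), protein, strrep("-", h))
  vapply(seq_len(nchar(protein)), function(i) {
    substr(padded, i, i + width - 1)
  }, "")
}

# Random S-centered window set with residues drawn uniformly.
random_windows <- function(n, width, seed, center = "S") {
  linmotif:::with_local_seed(seed, {
    m <- matrix(sample(AA, n * width, replace = TRUE), nrow = n)
    if (!is.null(center)) m[, (width + 1) / 2] <- center
    sequence_set(apply(m, 1, paste, collapse = ""))
  })
}

# Foreground with a planted pair: `k` of the n windows carry `residue` at
# `offset`; all other cells uniform random, center fixed to S.
planted_windows <- function(n, width, k, offset, residue, seed) {
  linmotif:::with_local_seed(seed, {
    m <- matrix(sample(AA, n * width, replace = TRUE), nrow = n)
    m[, (width + 1) / 2] <- "S"
    col <- offset + (width + 1) / 2
    m[, col] <- sample(setdiff(AA, residue), n, replace = TRUE)
    m[seq_len(k), col] <- residue
    sequence_set(apply(m, 1, paste, collapse = ""))
  })
}

motif_keys <- function(fit) {
  sort(method = "radix", vapply(fit$motifs, function(m) {
    paste(sprintf("%s@%+d", m$pairs$token, m$pairs$offset), collapse = ";")
  }, ""))
}

# serialize a fit's motif table to one string (byte-comparable)
serialize_motifs <- function(fit) {
  f <- tempfile()
  on.exit(unlink(f))
  write_motif_table(fit, f)
  paste(readLines(f), collapse = "\n")
}
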
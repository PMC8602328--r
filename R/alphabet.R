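# Amino-acid alphabet and small shared helpers.

# The 20 standard residues, alphabetical. All counting is restricted to these;
# the gap '-' (terminal padding) and ambiguity 'X' never enter numerator or
# denominator of any frequency.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

GAP <- "-"
UNKNOWN <- "X"

# Characters accepted in input windows after uppercasing; nonstandard residue
# codes are collapsed to 'X' on ingestion.
NONSTANDARD <- c("B", "J", "O", "U", "Z", "*")

#' Offsets of a window relative to its central position
#'
#' @param width Odd window width.
#' @return Integer vector `-(width-1)/2 ... +(width-1)/2`.
#' @keywords internal
window_offsets <- function(width) {
  h <- (width - 1L) %/% 2L
  seq.int(-h, h)
}

stopifnot_odd_width <- function(width) {
  if (length(width) != 1L || is.na(width) || width < 1L || width %% 2L == 0L) {
    stop("window width must be a single odd positive integer, got ", width)
  }
  invisible(as.integer(width))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so generators are pure in (args, seed).
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}
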
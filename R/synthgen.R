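# Synthetic data generators: the positional-bias demonstration set, random
# proteomes, and null foreground sampling. All generators are pure functions
# of their arguments and seed (byte-identical output for identical inputs).

#' Generate the positional-bias demonstration dataset
#'
#' Builds the 39-sequence, width-15 construction that separates tie-branching
#' extractors from greedy ones: 19 windows with D at offset -7, 19 with D at
#' offset +7, and a single window with D at both ends; every window has S at
#' the center and uniformly random residues elsewhere. The two enriched
#' positional residues are statistically identical, but share one sequence —
#' a greedy extractor captures that sequence for whichever pair it fixes
#' first, starving the other below a support threshold of 20.
#'
#' The construction makes the two enriched pairs exactly tied: the aspartic
#' acid counts at the two terminal positions are exactly 20 each (foreground
#' filler at those two columns excludes D), and the random background is
#' mirror-symmetric (every random window is included together with its
#' reverse), so the background frequency of D is bit-identical at offsets -7
#' and +7.
#'
#' @param seed Integer seed.
#' @param n_background Number of random S-centered background windows; rounded
#'   up to even for the mirror closure (default 3000).
#' @return List with `foreground` and `background` [sequence_set()]s.
#' @export
generate_bias_demo <- function(seed = 1L, n_background = 3000L) {
  width <- 15L
  center <- 8L
  with_local_seed(seed, {
    fg <- matrix(sample(AA20, 39L * width, replace = TRUE), nrow = 39L)
    # terminal columns: random but never D, so the planted counts are exact
    fg[, c(1L, width)] <- sample(setdiff(AA20, "D"), 39L * 2L, replace = TRUE)
    fg[, center] <- "S"
    fg[1:19, 1L] <- "D"
    fg[20:38, width] <- "D"
    fg[39L, c(1L, width)] <- "D"
    half <- ceiling(n_background / 2)
    bg <- matrix(sample(AA20, half * width, replace = TRUE), nrow = half)
    bg[, center] <- "S"
    bg <- rbind(bg, bg[, width:1L, drop = FALSE])
    list(foreground = sequence_set(apply_rows_paste(fg)),
         background = sequence_set(apply_rows_paste(bg)))
  })
}

#' Generate a random proteome
#'
#' I.i.d. residues drawn from the given frequencies (uniform over the 20
#' standard residues by default); a desk-scale stand-in for a reference
#' proteome in simulation studies.
#'
#' @param n_proteins Number of protein records.
#' @param protein_length Length of each protein.
#' @param frequencies Named residue probability vector over the 20 standard
#'   residues (must sum to 1); default uniform.
#' @param seed Integer seed.
#' @return Named character vector of protein sequences (`sp1`, `sp2`, ...).
#' @export
generate_proteome <- function(n_proteins, protein_length,
                              frequencies = NULL, seed = 1L) {
  if (is.null(frequencies)) {
    frequencies <- stats::setNames(rep(1 / 20, 20L), AA20)
  }
  stopifnot(setequal(names(frequencies), AA20),
            abs(sum(frequencies) - 1) < 1e-8)
  with_local_seed(seed, {
    chars <- sample(AA20, n_proteins * protein_length, replace = TRUE,
                    prob = frequencies[AA20])
    seqs <- vapply(seq_len(n_proteins), function(i) {
      paste(chars[((i - 1L) * protein_length + 1L):(i * protein_length)],
            collapse = "")
    }, "")
    stats::setNames(seqs, paste0("sp", seq_len(n_proteins)))
  })
}

#' Sample a null foreground from a background pool
#'
#' Draws `n` windows uniformly without replacement from a background window
#' pool (optionally restricted to a central residue). Because the foreground
#' is a random subset of the background population, no motif should be
#' enriched; the rate at which extraction still reports one estimates the
#' false-positive rate.
#'
#' @param pool A `background_model` or [sequence_set()] to sample from.
#' @param n Sample size (must not exceed the pool).
#' @param central_residue Optional central-residue restriction on the pool.
#' @param seed Integer seed.
#' @return A [sequence_set()] of `n` windows.
#' @export
sample_null <- function(pool, n, central_residue = NULL, seed = 1L) {
  windows <- if (inherits(pool, "background_model")) {
    apply_rows_paste(pool$mat)
  } else if (inherits(pool, "sequence_set")) {
    pool$windows
  } else {
    stop("pool must be a background_model or sequence_set")
  }
  if (!is.null(central_residue)) {
    w <- nchar(windows[1L])
    ctr <- substr(windows, (w + 1L) %/% 2L, (w + 1L) %/% 2L)
    windows <- windows[ctr == toupper(central_residue)]
  }
  if (n > length(windows)) {
    stop("sample size ", n, " exceeds pool of ", length(windows))
  }
  with_local_seed(seed, sequence_set(windows[sample.int(length(windows), n)]))
}

#' False-positive rate under null sampling
#'
#' Runs the complete null experiment: builds per-central-residue backgrounds
#' of `width`-mer windows from a proteome, draws replicate foregrounds of each
#' requested size uniformly without replacement from each background pool,
#' runs [motif_deconv()] with default settings, and reports the fraction of
#' replicates yielding at least one motif.
#'
#' @param proteome Named character vector of protein sequences.
#' @param width Window width (default 15).
#' @param sizes Foreground sample sizes (default `c(100, 10000)`); sizes
#'   exceeding a residue's pool are skipped for that residue.
#' @param reps Replicates per (central residue, size) stratum (default 25).
#' @param seed Integer seed; replicate seeds are derived from it.
#' @param ... Further arguments passed to [motif_deconv()].
#' @return List with `fraction` (replicates with >= 1 motif / total),
#'   `n_replicates`, `n_hits`, and a per-replicate data frame `detail`.
#' @export
null_fp_rate <- function(proteome, width = 15L, sizes = c(100L, 10000L),
                         reps = 25L, seed = 1L, ...) {
  stopifnot_odd_width(width)
  root <- build_background(proteome, width = width)
  center_col <- (width + 1L) %/% 2L
  centers <- root$mat[, center_col]
  residues <- AA20[AA20 %in% unique(centers)]
  detail <- list()
  counter <- 0L
  for (res in residues) {
    rows <- which(centers == res)
    pool <- sequence_set(apply_rows_paste(root$mat[rows, , drop = FALSE]))
    bg <- build_background(pool)
    for (size in sizes) {
      if (size > length(pool$windows)) next
      for (r in seq_len(reps)) {
        counter <- counter + 1L
        rep_seed <- (as.integer(seed) + 7919L * counter) %% 2147483647L
        fg <- sample_null(pool, size, seed = rep_seed)
        fit <- motif_deconv(fg, bg, ...)
        detail[[counter]] <- data.frame(
          central_residue = res, size = size, replicate = r,
          n_motifs = length(fit$motifs), stringsAsFactors = FALSE)
      }
    }
  }
  detail <- do.call(rbind, detail)
  n_hits <- sum(detail$n_motifs >= 1L)
  list(fraction = n_hits / nrow(detail), n_replicates = nrow(detail),
       n_hits = n_hits, detail = detail)
}
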
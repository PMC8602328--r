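# Statistical background: position-specific and pooled residue frequencies
# over a reference window population, with recursive reduction to the windows
# matching a motif prefix.

#' Build a background model
#'
#' The background defines the null residue frequencies against which
#' foreground enrichment is tested. It is built either from pre-aligned
#' windows (a [sequence_set()]) or from a proteome (named character vector of
#' protein sequences), in which case every residue position contributes one
#' window of the requested width, padded with `"-"` at the termini. When
#' `central_residue` is given, only windows centered on that residue are kept,
#' making background and site-centered foreground commensurate.
#'
#' Padded `"-"` cells and the ambiguity code `"X"` are excluded from both
#' numerator and denominator of every frequency.
#'
#' @param x A [sequence_set()] of background windows, or a (named) character
#'   vector of protein sequences.
#' @param width Odd window width; required for a proteome, taken from the set
#'   otherwise.
#' @param central_residue Optional single residue filter on window centers.
#' @return An object of class `background_model` with the window matrix,
#'   per-position residue counts, pooled counts and the fixed-pair prefix
#'   (empty for a root background).
#' @examples
#' bg <- build_background(c(p1 = "ASA"), width = 3)
#' bg$n
#' @export
build_background <- function(x, width = NULL, central_residue = NULL) {
  if (inherits(x, "sequence_set")) {
    if (!is.null(width) && width != x$width) {
      stop("background windows have width ", x$width, ", requested ", width)
    }
    width <- x$width
    mat <- seq_matrix(x)
  } else if (is.character(x)) {
    if (is.null(width)) stop("width is required for a proteome background")
    stopifnot_odd_width(width)
    mat <- do.call(rbind, lapply(x, enumerate_subwindows, width = width))
  } else {
    stop("background input must be a sequence_set or a character proteome")
  }
  center <- (width + 1L) %/% 2L
  if (!is.null(central_residue)) {
    central_residue <- toupper(central_residue)
    stopifnot(length(central_residue) == 1L, central_residue %in% AA20)
    mat <- mat[mat[, center] == central_residue, , drop = FALSE]
    if (nrow(mat) == 0L) {
      stop("no background windows with central residue '",
           central_residue, "'")
    }
  }
  if (nrow(mat) == 0L) stop("empty background")
  new_background(mat, width, central_residue, empty_pairs())
}

# every length-`width` window of a protein, one per residue position,
# '-'-padded at the termini
enumerate_subwindows <- function(protein, width) {
  chars <- strsplit(toupper(protein), "", fixed = TRUE)[[1]]
  chars[chars %in% NONSTANDARD] <- UNKNOWN
  h <- (width - 1L) %/% 2L
  padded <- c(rep(GAP, h), chars, rep(GAP, h))
  n <- length(chars)
  idx <- outer(seq_len(n), 0L:(width - 1L), `+`)
  matrix(padded[idx], nrow = n, ncol = width)
}

new_background <- function(mat, width, central_residue, fixed_prefix) {
  cnt <- residue_count_matrix(mat)
  structure(
    list(mat = mat, width = as.integer(width),
         counts = cnt, totals = colSums(cnt),
         pooled_counts = rowSums(cnt), pooled_total = sum(cnt),
         n = nrow(mat), central_residue = central_residue,
         fixed_prefix = fixed_prefix),
    class = "background_model"
  )
}

empty_pairs <- function() {
  data.frame(offset = integer(), token = character(),
             is_group = logical(), members = character(),
             stringsAsFactors = FALSE)
}

# 20 x width matrix of standard-residue counts per window column;
# '-' and 'X' cells contribute nowhere
residue_count_matrix <- function(mat) {
  code <- match(mat, AA20)
  colidx <- rep(seq_len(ncol(mat)), each = nrow(mat))
  keep <- !is.na(code)
  cnt <- matrix(
    tabulate((colidx[keep] - 1L) * 20L + code[keep], nbins = 20L * ncol(mat)),
    nrow = 20L, ncol = ncol(mat)
  )
  dimnames(cnt) <- list(AA20, as.character(window_offsets(ncol(mat))))
  cnt
}

#' @export
print.background_model <- function(x, ...) {
  cat("background_model:", x$n, "windows of width", x$width)
  if (!is.null(x$central_residue)) cat(", center", x$central_residue)
  if (nrow(x$fixed_prefix)) {
    cat(", reduced on", paste(sprintf("%s@%+d", x$fixed_prefix$token,
                                      x$fixed_prefix$offset),
                              collapse = " "))
  }
  cat("\n")
  invisible(x)
}

#' Background frequency of a residue or compound group at an offset
#'
#' @param bg A `background_model`.
#' @param offset Position relative to the window center, in
#'   `-(width-1)/2 ... +(width-1)/2`.
#' @param token A single residue, or the name of a compound group in `groups`.
#' @param position_specific If `TRUE` (default) use the per-position
#'   frequency; otherwise the frequency pooled over all positions.
#' @param groups Named list of compound groups (character vectors of member
#'   residues), consulted when `token` is not a single residue.
#' @return A probability; the frequency of a compound group is the sum over
#'   its (disjoint) member residues. Tokens absent from the background have
#'   frequency 0.
#' @export
bg_frequency <- function(bg, offset, token, position_specific = TRUE,
                         groups = NULL) {
  stopifnot(inherits(bg, "background_model"))
  members <- resolve_token(token, groups)
  col <- offset_to_col(bg$width, offset)
  if (position_specific) {
    tot <- unname(bg$totals[col])
    if (tot == 0) return(0)
    unname(sum(bg$counts[members, col]) / tot)
  } else {
    if (bg$pooled_total == 0) return(0)
    unname(sum(bg$pooled_counts[members]) / bg$pooled_total)
  }
}

resolve_token <- function(token, groups) {
  if (token %in% AA20) return(token)
  if (!is.null(groups) && token %in% names(groups)) return(groups[[token]])
  stop("unknown token '", token, "'")
}

offset_to_col <- function(width, offset) {
  h <- (width - 1L) %/% 2L
  if (offset < -h || offset > h) {
    stop("offset ", offset, " outside window of width ", width)
  }
  offset + h + 1L
}

#' Reduce a background to the windows matching fixed pairs
#'
#' Re-compiles the background over the subset of its windows that match every
#' fixed (offset, token) pair, extending the model's prefix. This is the
#' recursive-background step: each foreground subset is tested against the
#' correspondingly restricted null population.
#'
#' @param bg A `background_model`.
#' @param pairs Data frame with columns `offset`, `token`, and optionally
#'   `is_group`/`members` (as produced by the engine); an empty frame returns
#'   `bg` unchanged.
#' @param groups Named list of compound groups used to resolve group tokens.
#' @return The reduced `background_model`, or `NULL` when no background window
#'   matches ("background exhausted" — callers terminate that branch).
#' @export
reduce_background <- function(bg, pairs, groups = NULL) {
  stopifnot(inherits(bg, "background_model"))
  if (is.null(pairs) || nrow(pairs) == 0L) return(bg)
  if (anyDuplicated(pairs$offset)) {
    stop("fixed pairs must have unique offsets")
  }
  keep <- rep(TRUE, nrow(bg$mat))
  for (i in seq_len(nrow(pairs))) {
    members <- pair_members(pairs[i, ], groups)
    keep <- keep & bg$mat[, offset_to_col(bg$width, pairs$offset[i])] %in%
      members
  }
  if (!any(keep)) return(NULL)
  prefix <- rbind(bg$fixed_prefix, canonical_pairs(pairs, groups))
  new_background(bg$mat[keep, , drop = FALSE], bg$width,
                 bg$central_residue, prefix)
}

pair_members <- function(pair, groups) {
  if (!is.null(pair$members) && !is.na(pair$members) && nzchar(pair$members) &&
      isTRUE(pair$is_group)) {
    strsplit(pair$members, "", fixed = TRUE)[[1]]
  } else {
    resolve_token(pair$token, groups)
  }
}

# normalize a pairs frame to the canonical 4-column layout
canonical_pairs <- function(pairs, groups = NULL) {
  out <- data.frame(offset = as.integer(pairs$offset),
                    token = as.character(pairs$token),
                    stringsAsFactors = FALSE)
  out$is_group <- if ("is_group" %in% names(pairs)) as.logical(pairs$is_group)
    else !(out$token %in% AA20)
  out$members <- if ("members" %in% names(pairs) &&
                     !all(is.na(pairs$members))) as.character(pairs$members)
    else vapply(seq_len(nrow(out)), function(i) {
      paste(resolve_token(out$token[i], groups), collapse = "")
    }, "")
  out
}
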
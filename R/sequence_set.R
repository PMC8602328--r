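#' Construct a set of fixed-width aligned sequence windows
#'
#' A `sequence_set` holds peptide windows of a common odd width, aligned on a
#' central position (the modified site when windows are site-centered).
#' Windows are uppercased; nonstandard residue codes (B, J, O, U, Z, *) are
#' collapsed to `"X"`, which is excluded from all frequency calculations.
#' Terminal overhang beyond a protein's ends is padded with `"-"`, which is
#' only legal as a contiguous prefix and/or suffix.
#'
#' @param windows Character vector of equal-length sequences.
#' @param sample Optional character vector of per-window sample/tissue labels
#'   (recycled if length 1).
#' @param intensity Optional numeric vector of per-window non-negative
#'   intensities; `NA` marks a missing measurement.
#' @param source Optional data frame with one row per window giving the
#'   originating site (columns `accession`, `position`, `modification`).
#' @return An object of class `sequence_set` with elements `windows`, `width`,
#'   `central_index` (1-based column of the central position), and optional
#'   `sample`, `intensity`, `source`.
#' @examples
#' ss <- sequence_set(c("AAASAAA", "CCCSCCC"))
#' ss$width
#' @export
sequence_set <- function(windows, sample = NULL, intensity = NULL,
                         source = NULL) {
  if (length(windows) == 0L) {
    stop("a sequence_set needs at least one window")
  }
  windows <- normalize_windows(windows)
  w <- unique(nchar(windows))
  if (length(w) != 1L) {
    bad <- which(nchar(windows) != nchar(windows[1L]))[1L]
    stop("inconsistent width at line ", bad, ": expected ",
         nchar(windows[1L]), ", got ", nchar(windows[bad]))
  }
  stopifnot_odd_width(w)
  check_window_chars(windows)
  if (!is.null(sample)) {
    if (length(sample) == 1L) sample <- rep(sample, length(windows))
    stopifnot(length(sample) == length(windows))
    sample <- as.character(sample)
  }
  if (!is.null(intensity)) {
    stopifnot(length(intensity) == length(windows))
    intensity <- as.numeric(intensity)
    if (any(intensity < 0, na.rm = TRUE)) {
      stop("intensities must be non-negative")
    }
  }
  if (!is.null(source)) {
    stopifnot(is.data.frame(source), nrow(source) == length(windows))
  }
  structure(
    list(windows = windows, width = as.integer(w),
         central_index = (as.integer(w) + 1L) %/% 2L,
         sample = sample, intensity = intensity, source = source),
    class = "sequence_set"
  )
}

normalize_windows <- function(windows) {
  windows <- toupper(as.character(windows))
  # collapse nonstandard residue codes to the ambiguity character
  chartr(paste(NONSTANDARD, collapse = ""),
         strrep(UNKNOWN, length(NONSTANDARD)), windows)
}

check_window_chars <- function(windows) {
  ok <- grepl(sprintf("^-*[%sX]+-*$", paste(AA20, collapse = "")), windows)
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop("invalid window at line ", bad, ": '", windows[bad],
         "' (only the 20 standard residues, 'X' and terminal '-' padding ",
         "are allowed)")
  }
  invisible(TRUE)
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("sequence_set:", length(x$windows), "windows of width", x$width, "\n")
  if (!is.null(x$sample)) {
    cat("  samples:", paste(utils::head(unique(x$sample), 8L),
                            collapse = ", "), "\n")
  }
  n <- min(length(x$windows), 5L)
  cat(paste0("  ", x$windows[seq_len(n)], collapse = "\n"), "\n")
  if (length(x$windows) > n) cat("  ...\n")
  invisible(x)
}

#' @export
length.sequence_set <- function(x) length(x$windows)

#' Subset a sequence set by window index
#'
#' @param x A `sequence_set`.
#' @param i Integer or logical index over windows.
#' @param ... Ignored.
#' @return A `sequence_set` with the selected windows (labels, intensities and
#'   source rows follow along).
#' @export
`[.sequence_set` <- function(x, i, ...) {
  sequence_set(x$windows[i],
               sample = if (!is.null(x$sample)) x$sample[i],
               intensity = if (!is.null(x$intensity)) x$intensity[i],
               source = if (!is.null(x$source)) x$source[i, , drop = FALSE])
}

# n x width character matrix of a window vector (internal workhorse)
window_matrix <- function(windows, width) {
  matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
         nrow = length(windows), ncol = width, byrow = TRUE)
}

seq_matrix <- function(set) window_matrix(set$windows, set$width)

#' Reverse every window in a sequence set
#'
#' Character-reverses each window (N/C orientation flip). Used for the
#' reversal-equivariance validation: a robust extractor must report the same
#' motifs, with negated offsets, when foreground and background are both
#' reversed.
#'
#' @param set A `sequence_set`.
#' @return A `sequence_set` of the reversed windows.
#' @examples
#' reverse_windows(sequence_set("AAASDDD"))$windows  # "DDDSAAA"
#' @export
reverse_windows <- function(set) {
  stopifnot(inherits(set, "sequence_set"))
  m <- seq_matrix(set)[, set$width:1L, drop = FALSE]
  out <- set
  out$windows <- apply_rows_paste(m)
  out
}

apply_rows_paste <- function(m) {
  do.call(paste0, lapply(seq_len(ncol(m)), function(j) m[, j]))
}
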
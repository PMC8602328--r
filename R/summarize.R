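# Post-extraction analytics: exact pattern matching across samples or
# modifications, significance-filtered percentage matrices, positional load,
# composition differentials, abundance aggregation and clustering-ready
# transforms.

#' Does a window exactly match a motif?
#'
#' A window matches iff at every fixed offset its residue equals the fixed
#' token (or belongs to the fixed compound group); padding `"-"` and the
#' ambiguity code `"X"` never match.
#'
#' @param window A window string or [sequence_set()].
#' @param motif A motif (element of a fit's `motifs`).
#' @return Logical, one value per window.
#' @export
matches <- function(window, motif) {
  set <- if (inherits(window, "sequence_set")) window
    else sequence_set(window)
  stopifnot(set$width == motif$width)
  fmat <- seq_matrix(set)
  hit <- rep(TRUE, nrow(fmat))
  for (i in seq_len(nrow(motif$pairs))) {
    hit <- hit & match_pair_matrix(fmat, motif$pairs$offset[i],
                                   motif$pairs$members[i])
  }
  hit
}

# windows x motifs logical match matrix
match_motifs <- function(set, motifs) {
  out <- vapply(motifs, function(m) matches(set, m),
                logical(length(set$windows)))
  out <- matrix(out, nrow = length(set$windows), ncol = length(motifs))
  colnames(out) <- vapply(motifs, `[[`, "", "pattern")
  out
}

# drop motifs with identical fixed-pair sets, keeping the best supported
dedup_motifs <- function(motifs) {
  if (length(motifs) <= 1L) return(motifs)
  finalize_motifs(motifs)
}

#' Build a motifs x groups pattern match matrix
#'
#' Counts, for every motif and every sample/modification group, the windows
#' exactly matching the motif's fixed pairs; tests each count against the
#' expected match probability under the background (product of the per-offset
#' background frequencies of the fixed pairs) with the one-sided binomial
#' test, Bonferroni-corrected over motifs x groups; and converts significant
#' counts to percentages of the group size. Non-significant cells are masked
#' (`NA`) in the percentage matrix.
#'
#' @param motifs List of motifs, possibly pooled from several fits (duplicated
#'   fixed-pair sets are collapsed).
#' @param grouped_sets Named list of [sequence_set()], one per group; widths
#'   must agree.
#' @param background A `background_model` of the same width.
#' @param alpha Pre-correction significance level (default 0.001).
#' @param position_specific_background Use per-position background
#'   frequencies for the expected match probability (default `TRUE`).
#' @return An object of class `pattern_match_matrix`: list with `counts`,
#'   `pvalues`, `percent` (masked), `expected_p` per motif, `group_sizes`,
#'   `motifs` and `alpha`.
#' @export
build_match_matrix <- function(motifs, grouped_sets, background,
                               alpha = 0.001,
                               position_specific_background = TRUE) {
  stopifnot(length(grouped_sets) >= 1L, !is.null(names(grouped_sets)))
  motifs <- dedup_motifs(motifs)
  if (length(motifs) == 0L) stop("no motifs to match")
  widths <- vapply(grouped_sets, `[[`, 0L, "width")
  if (length(unique(widths)) != 1L || widths[1L] != background$width) {
    stop("all groups and the background must share one width")
  }
  patterns <- vapply(motifs, `[[`, "", "pattern")
  counts <- vapply(grouped_sets, function(set) {
    colSums(match_motifs(set, motifs))
  }, numeric(length(motifs)))
  counts <- matrix(as.integer(counts), nrow = length(motifs),
                   dimnames = list(patterns, names(grouped_sets)))
  group_sizes <- vapply(grouped_sets, function(s) length(s$windows), 0L)
  expected_p <- vapply(motifs, function(m) {
    prod(vapply(seq_len(nrow(m$pairs)), function(i) {
      mem <- strsplit(m$pairs$members[i], "", fixed = TRUE)[[1]]
      sum(vapply(mem, function(r) {
        bg_frequency(background, m$pairs$offset[i], r,
                     position_specific = position_specific_background)
      }, 0))
    }, 0))
  }, 0)
  pvalues <- counts
  pvalues[] <- binomial_pvalue(as.vector(counts),
                               rep(group_sizes, each = length(motifs)),
                               rep(expected_p, times = length(group_sizes)))
  m_tests <- length(motifs) * length(grouped_sets)
  significant <- pvalues <= alpha / m_tests & counts > 0L
  percent <- 100 * sweep(counts, 2L, group_sizes, `/`)
  percent[!significant] <- NA_real_
  structure(
    list(counts = counts, pvalues = pvalues, percent = percent,
         significant = significant, expected_p = expected_p,
         group_sizes = group_sizes, motifs = motifs, alpha = alpha,
         m_tests = m_tests),
    class = "pattern_match_matrix"
  )
}

#' @export
print.pattern_match_matrix <- function(x, ...) {
  cat("pattern_match_matrix:", nrow(x$counts), "motifs x",
      ncol(x$counts), "groups;",
      sum(x$significant), "significant cells (alpha", x$alpha,
      "Bonferroni over", x$m_tests, "tests)\n")
  print(round(x$percent, 2))
  invisible(x)
}

#' Positional load of motif sets
#'
#' For each group, the percentage of its motifs that fix any residue (or
#' group) at each window offset.
#'
#' @param motifs_by_group Named list: one list of motifs per group (each group
#'   must have at least one motif).
#' @param width Window width.
#' @return Numeric matrix groups x offsets of percentages in `[0, 100]`.
#' @export
positional_load <- function(motifs_by_group, width) {
  stopifnot_odd_width(width)
  stopifnot(all(lengths(motifs_by_group) >= 1L))
  offsets <- window_offsets(width)
  out <- t(vapply(motifs_by_group, function(motifs) {
    fixed <- vapply(motifs, function(m) offsets %in% m$pairs$offset,
                    logical(length(offsets)))
    100 * rowMeans(matrix(fixed, nrow = length(offsets)))
  }, numeric(length(offsets))))
  colnames(out) <- as.character(offsets)
  out
}

#' Differential fixed-residue composition between two motif sets
#'
#' Tallies every fixed (offset, token) pair over each motif set, converts the
#' tallies to percentages of each set's total, and reports the log2 ratio of
#' the two percentages. Pairs present in only one set, or in neither, carry a
#' status sentinel instead of a finite ratio.
#'
#' @param motifs_a,motifs_b Lists of motifs for the two modification types.
#' @return Data frame with `offset`, `token`, `pct_a`, `pct_b`, `log2_ratio`
#'   (finite only for `status == "both"`), `status` (one of `both`, `a_only`,
#'   `b_only`, `absent`) and `combined_pct` (pooled percentage over both sets,
#'   for point-size encoding in dot plots).
#' @export
composition_differential <- function(motifs_a, motifs_b) {
  tally <- function(motifs) {
    pairs <- do.call(rbind, lapply(motifs, `[[`, "pairs"))
    if (is.null(pairs) || nrow(pairs) == 0L) {
      return(data.frame(offset = integer(), token = character(),
                        n = integer(), stringsAsFactors = FALSE))
    }
    agg <- stats::aggregate(list(n = rep(1L, nrow(pairs))),
                            by = list(offset = pairs$offset,
                                      token = pairs$token), FUN = sum)
    agg
  }
  a <- tally(motifs_a)
  b <- tally(motifs_b)
  key <- function(d) paste(d$offset, d$token, sep = "@")
  all_keys <- sort(unique(c(key(a), key(b))), method = "radix")
  na <- a$n[match(all_keys, key(a))]
  nb <- b$n[match(all_keys, key(b))]
  na[is.na(na)] <- 0L
  nb[is.na(nb)] <- 0L
  pct_a <- if (sum(na) > 0) 100 * na / sum(na) else rep(0, length(na))
  pct_b <- if (sum(nb) > 0) 100 * nb / sum(nb) else rep(0, length(nb))
  status <- ifelse(na > 0 & nb > 0, "both",
                   ifelse(na > 0, "a_only",
                          ifelse(nb > 0, "b_only", "absent")))
  log2_ratio <- rep(NA_real_, length(na))
  both <- status == "both"
  log2_ratio[both] <- log2(pct_a[both] / pct_b[both])
  tot <- sum(na) + sum(nb)
  parts <- strsplit(all_keys, "@", fixed = TRUE)
  data.frame(
    offset = as.integer(vapply(parts, `[`, "", 1L)),
    token = vapply(parts, `[`, "", 2L),
    pct_a = pct_a, pct_b = pct_b, log2_ratio = log2_ratio,
    status = status,
    combined_pct = if (tot > 0) 100 * (na + nb) / tot else rep(0, length(na)),
    stringsAsFactors = FALSE
  )
}

#' Mean matched intensity per motif and condition
#'
#' For every motif and every condition (group), the arithmetic mean of the
#' intensities of the condition's windows matching the motif. Missing
#' intensities are excluded from the mean; a motif with no matching window in
#' a condition yields `NA`, never 0.
#'
#' @param grouped_sets Named list of [sequence_set()] carrying intensities.
#' @param motifs List of motifs.
#' @return Numeric matrix motifs x conditions.
#' @export
abundance_matrix <- function(grouped_sets, motifs) {
  stopifnot(length(motifs) >= 1L)
  out <- vapply(grouped_sets, function(set) {
    if (is.null(set$intensity)) {
      stop("abundance_matrix needs intensities on every group")
    }
    hits <- match_motifs(set, motifs)
    vapply(seq_along(motifs), function(j) {
      v <- set$intensity[hits[, j]]
      v <- v[!is.na(v)]
      if (length(v) == 0L) NA_real_ else mean(v)
    }, 0)
  }, numeric(length(motifs)))
  out <- matrix(out, nrow = length(motifs),
                dimnames = list(vapply(motifs, `[[`, "", "pattern"),
                                names(grouped_sets)))
  out
}

#' ln(x+1) transform with row centering and unit-variance scaling
#'
#' The standard pre-clustering transform for count matrices: elementwise
#' `log(x + 1)`, then per-row mean subtraction, then per-row division by the
#' row standard deviation. Rows with zero variance become all-zero rows (they
#' carry no contrast but keep the matrix shape stable).
#'
#' @param x Non-negative numeric matrix.
#' @return The transformed matrix, same shape and dimnames.
#' @export
transform_counts <- function(x) {
  stopifnot(is.matrix(x), all(x >= 0, na.rm = TRUE))
  y <- log1p(x)
  ctr <- y - rowMeans(y)
  sdv <- apply(ctr, 1L, stats::sd)
  out <- ctr / ifelse(sdv > 0, sdv, 1)
  out[sdv == 0, ] <- 0
  out
}

#' Order a matrix by average-linkage hierarchical clustering
#'
#' Clusters rows (and, when the matrix has more than two columns, columns)
#' by agglomerative average linkage on Euclidean distances and returns the
#' reordered matrix together with the dendrogram merge lists, ready for
#' heatmap rendering or downstream linkage consumers.
#'
#' @param x Numeric matrix without missing values (mask non-significant cells
#'   to 0 first, e.g. from a [build_match_matrix()] percent matrix).
#' @param cluster_columns Also cluster columns (default `TRUE` when `ncol > 2`).
#' @return List with `matrix` (reordered), `row_order`, `col_order`,
#'   `row_merges` and `col_merges` (data frames with columns `a`, `b`,
#'   `height`; negative entries are leaves, positive entries earlier merges,
#'   as in [stats::hclust()]).
#' @export
cluster_export <- function(x, cluster_columns = ncol(x) > 2L) {
  stopifnot(is.matrix(x), !anyNA(x))
  cl_rows <- if (nrow(x) > 1L) {
    stats::hclust(stats::dist(x, method = "euclidean"), method = "average")
  }
  cl_cols <- if (cluster_columns && ncol(x) > 1L) {
    stats::hclust(stats::dist(t(x), method = "euclidean"), method = "average")
  }
  row_order <- if (is.null(cl_rows)) seq_len(nrow(x)) else cl_rows$order
  col_order <- if (is.null(cl_cols)) seq_len(ncol(x)) else cl_cols$order
  merge_df <- function(cl) {
    if (is.null(cl)) {
      return(data.frame(a = integer(), b = integer(), height = numeric()))
    }
    data.frame(a = cl$merge[, 1L], b = cl$merge[, 2L], height = cl$height)
  }
  list(matrix = x[row_order, col_order, drop = FALSE],
       row_order = row_order, col_order = col_order,
       row_merges = merge_df(cl_rows), col_merges = merge_df(cl_cols))
}

#' Write a labelled matrix as TSV
#'
#' @param x Matrix with dimnames.
#' @param path Output path.
#' @param na Representation for missing (masked) cells.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path, na = "NA") {
  df <- data.frame(row = rownames(x) %||% as.character(seq_len(nrow(x))),
                   x, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = na)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write dendrogram merges as a TSV edge list
#'
#' @param merges Merge data frame from [cluster_export()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_tsv <- function(merges, path) {
  utils::write.table(merges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
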
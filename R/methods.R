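# S3 methods for motif_deconv fits.

#' @export
print.motif_deconv <- function(x, ...) {
  cat("Linear motif deconvolution\n")
  cat("  foreground: ", length(x$foreground), " windows of width ",
      x$foreground$width, " (", x$n_input, " input",
      if (x$n_rejected_central)
        paste0(", ", x$n_rejected_central, " rejected on central residue"),
      if (x$n_duplicates_removed)
        paste0(", ", x$n_duplicates_removed, " duplicates removed"),
      ")\n", sep = "")
  cat("  background: ", x$background$n, " windows\n", sep = "")
  cat("  alpha ", x$config$alpha, " (Bonferroni), min support ",
      x$config$min_support, ", ",
      if (x$config$position_specific_background) "position-specific"
      else "pooled", " background",
      if (length(x$config$compound_groups))
        paste0(", ", length(x$config$compound_groups), " compound groups"),
      "\n", sep = "")
  if (length(x$motifs) == 0L) {
    cat("  no enriched motifs\n")
  } else {
    cat("  ", length(x$motifs), " motif(s):\n", sep = "")
    df <- motif_table(x$motifs)
    print(df[, c("pattern", "fixed_pairs", "support", "class")],
          row.names = FALSE)
  }
  invisible(x)
}

#' Summarize a motif deconvolution fit
#'
#' @param object A `motif_deconv` fit.
#' @param ... Ignored.
#' @return A data frame with one row per motif (`pattern`, `fixed_pairs`,
#'   `support`, `class`, per-pair p-values, `n_matched`), of class
#'   `summary.motif_deconv`.
#' @export
summary.motif_deconv <- function(object, ...) {
  df <- motif_table(object$motifs)
  attr(df, "n_foreground") <- length(object$foreground)
  attr(df, "class_counts") <- table(factor(df$class, c("I", "II", "III")))
  class(df) <- c("summary.motif_deconv", class(df))
  df
}

#' @export
print.summary.motif_deconv <- function(x, ...) {
  cc <- attr(x, "class_counts")
  cat(nrow(x), "motif(s) over", attr(x, "n_foreground"), "windows;",
      "complexity classes I/II/III:", paste(cc, collapse = "/"), "\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Match new windows against the motifs of a fit
#'
#' @param object A `motif_deconv` fit.
#' @param newdata A [sequence_set()] (default: the fit's own foreground).
#' @param ... Ignored.
#' @return Logical matrix, windows x motifs (columns named by pattern), where
#'   `TRUE` means the window exactly matches all fixed pairs of the motif.
#' @export
predict.motif_deconv <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$foreground
  stopifnot(inherits(newdata, "sequence_set"))
  match_motifs(newdata, object$motifs)
}

#' Plot motif support by complexity class
#'
#' Horizontal bar chart of motif support, shaded by complexity class
#' (I: central + flanking fixed; II: central only; III: flanking only).
#'
#' @param x A `motif_deconv` fit.
#' @param ... Passed to [graphics::barplot()].
#' @return The fit, invisibly.
#' @export
plot.motif_deconv <- function(x, ...) {
  if (length(x$motifs) == 0L) {
    graphics::plot.new()
    graphics::title(main = "no enriched motifs")
    return(invisible(x))
  }
  df <- motif_table(x$motifs)
  df <- df[nrow(df):1L, , drop = FALSE]
  shade <- c(I = "grey20", II = "grey55", III = "grey80")[df$class]
  op <- graphics::par(mar = c(4, 10, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(df$support, names.arg = df$pattern, horiz = TRUE,
                    las = 1, col = shade, xlab = "support (sequences)", ...)
  graphics::legend("bottomright", legend = paste("class", c("I", "II", "III")),
                   fill = c("grey20", "grey55", "grey80"), bty = "n")
  invisible(x)
}
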
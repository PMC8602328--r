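# Core motif deconvolution: positional enrichment scanning, simultaneous
# selection of all maximally enriched pairs, overlapping-subset partitioning
# with background re-compilation, and recursive motif assembly.

#' One-sided exact binomial tail probability
#'
#' P(X >= k) for X ~ Binomial(n, p0), evaluated through the stable survival
#' form of the binomial distribution function (never as 1 - CDF in floating
#' point). Vectorized over its arguments.
#'
#' @param k Observed count(s), `0 <= k <= n`.
#' @param n Number of trials.
#' @param p0 Null success probability.
#' @param log.p Return the natural log of the tail probability.
#' @return The upper-tail probability (or its log).
#' @examples
#' binomial_pvalue(0, 10, 0.3)  # 1
#' binomial_pvalue(3, 3, 0.5)   # 0.125
#' @export
binomial_pvalue <- function(k, n, p0, log.p = FALSE) {
  stopifnot(all(k >= 0), all(k <= n), all(p0 >= 0), all(p0 <= 1))
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE, log.p = log.p)
}

new_engine_config <- function(alpha = 0.001, min_support = 20L,
                              position_specific_background = TRUE,
                              compound_groups = NULL,
                              central_residue = NULL,
                              dedup_sequences = FALSE,
                              tie_select = c("branch", "greedy"),
                              tie_tol = 1e-9) {
  stopifnot(alpha > 0, alpha < 1, min_support >= 1)
  tie_select <- match.arg(tie_select)
  if (identical(compound_groups, "default")) {
    compound_groups <- default_compound_groups()
  } else if (is.character(compound_groups) && length(compound_groups) == 1L &&
             !identical(compound_groups, "off")) {
    compound_groups <- read_compound_groups(compound_groups)
  } else if (identical(compound_groups, "off")) {
    compound_groups <- NULL
  }
  compound_groups <- validate_groups(compound_groups)
  if (!is.null(central_residue)) {
    central_residue <- toupper(central_residue)
    stopifnot(all(central_residue %in% AA20))
  }
  list(alpha = alpha, min_support = as.integer(min_support),
       position_specific_background = isTRUE(position_specific_background),
       compound_groups = compound_groups,
       central_residue = central_residue,
       dedup_sequences = isTRUE(dedup_sequences),
       tie_select = tie_select, tie_tol = tie_tol)
}

# --- enrichment scan -------------------------------------------------------

# Scan a foreground window matrix against a background model. Returns one row
# per (offset, token) candidate with k > 0; the Bonferroni family size m is
# width * (20 + number of groups) regardless of how many candidates have
# support.
scan_matrix <- function(fmat, bg, cfg) {
  width <- ncol(fmat)
  offsets <- window_offsets(width)
  groups <- cfg$compound_groups
  ngroups <- length(groups)
  m_tests <- width * (20L + ngroups)

  fg_counts <- residue_count_matrix(fmat)        # 20 x width
  fg_totals <- colSums(fg_counts)                # counted residues per column

  if (cfg$position_specific_background) {
    bg_tot <- bg$totals
    p0_single <- sweep(bg$counts, 2L, ifelse(bg_tot > 0, bg_tot, 1L), `/`)
    p0_single[, bg_tot == 0] <- 0
  } else {
    pooled <- if (bg$pooled_total > 0) bg$pooled_counts / bg$pooled_total
      else rep(0, 20L)
    p0_single <- matrix(pooled, nrow = 20L, ncol = width,
                        dimnames = dimnames(bg$counts))
  }

  offset <- rep(offsets, each = 20L)
  token <- rep(AA20, times = width)
  is_group <- rep(FALSE, 20L * width)
  members <- token
  kvec <- as.vector(fg_counts)
  p0vec <- as.vector(p0_single)
  nvec <- rep(fg_totals, each = 20L)

  if (ngroups > 0L) {
    gk <- do.call(rbind, lapply(groups, function(g) {
      colSums(fg_counts[g, , drop = FALSE])
    }))
    gp0 <- do.call(rbind, lapply(groups, function(g) {
      colSums(p0_single[g, , drop = FALSE])
    }))
    offset <- c(offset, rep(offsets, each = ngroups))
    token <- c(token, rep(names(groups), times = width))
    is_group <- c(is_group, rep(TRUE, ngroups * width))
    members <- c(members,
                 rep(vapply(groups, paste, "", collapse = ""), times = width))
    kvec <- c(kvec, as.vector(gk))
    p0vec <- c(p0vec, as.vector(gp0))
    nvec <- c(nvec, rep(fg_totals, each = ngroups))
  }

  res <- data.frame(offset = offset, token = token, is_group = is_group,
                    members = members, k = kvec, n = nvec, p0 = p0vec,
                    stringsAsFactors = FALSE)
  res <- res[res$k > 0L, , drop = FALSE]
  res$log_p <- binomial_pvalue(res$k, res$n, res$p0, log.p = TRUE)
  res$p <- exp(res$log_p)
  res$m <- m_tests
  res$significant <- res$log_p <= log(cfg$alpha / m_tests)
  # deterministic candidate order: offset ascending, singles before groups,
  # token alphabetical
  res <- res[order(res$offset, res$is_group, res$token,
                   method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Scan positional enrichment of a foreground against a background
#'
#' Tests every (offset, residue-or-group) pair with a foreground count
#' `k > 0` using the one-sided exact binomial test against the background
#' frequency, Bonferroni-corrected over the full candidate family
#' `m = width * (20 + number of compound groups)`.
#'
#' @param foreground A [sequence_set()].
#' @param background A `background_model` of the same width.
#' @param alpha Significance level before Bonferroni correction.
#' @param position_specific_background Use per-position background
#'   frequencies (`TRUE`, default) or frequencies pooled over all positions.
#' @param compound_groups `NULL` (off), `"default"`, a group file path, or a
#'   named list of residue groups.
#' @return Data frame with one row per candidate: `offset`, `token`,
#'   `is_group`, `members`, `k`, `n` (foreground windows with a counted
#'   residue at the offset), `p0`, `p`, `log_p`, `m`, `significant`.
#' @export
scan_enrichment <- function(foreground, background, alpha = 0.001,
                            position_specific_background = TRUE,
                            compound_groups = NULL) {
  stopifnot(inherits(foreground, "sequence_set"),
            inherits(background, "background_model"),
            foreground$width == background$width)
  cfg <- new_engine_config(alpha = alpha,
                           position_specific_background =
                             position_specific_background,
                           compound_groups = compound_groups)
  scan_matrix(seq_matrix(foreground), background, cfg)
}

#' Select all maximally enriched significant pairs
#'
#' Among significant scan results, returns every pair whose p-value ties the
#' minimum (equality of log p-values within a relative tolerance, so that
#' mathematically identical configurations computed in different orders still
#' tie). When a single residue and a compound group containing it are both
#' maximal at the same offset with identical support, only the more specific
#' single residue is kept.
#'
#' @param results Scan data frame from [scan_enrichment()].
#' @param tol Relative tolerance on log p-values for tie detection.
#' @param min_support Only pairs with foreground count `k >= min_support` are
#'   eligible: fixing a pair yields the subset of windows matching it, so a
#'   pair below the motif support threshold could never extend to an emittable
#'   motif and would only starve its branch (this also disarms zero-background
#'   singleton artifacts in small reduced backgrounds).
#' @return The selected rows, ordered by offset then token (singles before
#'   groups); zero rows when nothing is significant.
#' @export
select_maximal <- function(results, tol = 1e-9, min_support = 1L) {
  sig <- results[results$significant & results$k >= min_support, ,
                 drop = FALSE]
  if (nrow(sig) == 0L) return(sig)
  lmin <- min(sig$log_p)
  tied <- if (is.infinite(lmin)) is.infinite(sig$log_p) & sig$log_p < 0
    else abs(sig$log_p - lmin) <= tol * max(1, abs(lmin))
  sel <- sig[tied, , drop = FALSE]
  # specificity tie-break: drop a group when a maximal member single at the
  # same offset has the same support (the group adds no sequences)
  if (any(sel$is_group)) {
    drop <- vapply(seq_len(nrow(sel)), function(i) {
      if (!sel$is_group[i]) return(FALSE)
      mem <- strsplit(sel$members[i], "", fixed = TRUE)[[1]]
      any(!sel$is_group & sel$offset == sel$offset[i] &
            sel$token %in% mem & sel$k == sel$k[i])
    }, NA)
    sel <- sel[!drop, , drop = FALSE]
  }
  sel <- sel[order(sel$offset, sel$is_group, sel$token,
                   method = "radix"), , drop = FALSE]
  rownames(sel) <- NULL
  sel
}

# logical: which rows of fmat match a single (offset, members) pair
match_pair_matrix <- function(fmat, offset, members) {
  fmat[, offset_to_col(ncol(fmat), offset)] %in%
    strsplit(members, "", fixed = TRUE)[[1]]
}

#' Partition a foreground over selected pairs
#'
#' Splits a foreground into one (possibly overlapping) subset per pair — all
#' windows matching that pair — and the remainder of windows matching none.
#' A window carrying several selected pairs lands in all of their subsets and
#' leaves the remainder; every window is therefore in at least one subset or
#' in the remainder, never both.
#'
#' @param foreground A [sequence_set()].
#' @param pairs Data frame of pairs (columns `offset`, `token`, optional
#'   `is_group`/`members`), e.g. from [select_maximal()].
#' @param groups Named list of compound groups for resolving group tokens.
#' @return List with `subsets` (named list of [sequence_set()], names
#'   `token@offset`) and `remainder` (a [sequence_set()] or `NULL` when
#'   empty).
#' @export
partition <- function(foreground, pairs, groups = NULL) {
  stopifnot(inherits(foreground, "sequence_set"), nrow(pairs) > 0L)
  pairs <- canonical_pairs(pairs, groups)
  fmat <- seq_matrix(foreground)
  hits <- lapply(seq_len(nrow(pairs)), function(i) {
    match_pair_matrix(fmat, pairs$offset[i], pairs$members[i])
  })
  names(hits) <- sprintf("%s@%+d", pairs$token, pairs$offset)
  any_hit <- Reduce(`|`, hits)
  subsets <- lapply(hits, function(h) {
    if (any(h)) foreground[h] else NULL
  })
  remainder <- if (all(any_hit)) NULL else foreground[!any_hit]
  list(subsets = subsets, remainder = remainder)
}

# --- recursion -------------------------------------------------------------

#' Deconvolve linear motifs from aligned sequence windows
#'
#' Fits the recursive motif model: at each node, every positional
#' residue/group candidate is tested for enrichment against the (recursively
#' reduced) background; all equally, maximally enriched significant pairs are
#' fixed simultaneously, the foreground is partitioned into possibly
#' overlapping subsets (one per fixed pair, co-matching pairs merged into one
#' branch) plus a remainder, the background is re-compiled for each subset,
#' and the procedure recurses. A branch terminates, emitting its accumulated
#' fixed pairs as a motif, when no further candidate is significant (or its
#' reduced background is exhausted) and its support meets `min_support`;
#' remainder branches extend existing prefixes but never re-emit them. The
#' algorithm consumes only counts, so results are invariant to the order of
#' the input windows.
#'
#' @param foreground A [sequence_set()] of aligned windows, or a path to a
#'   pre-aligned text file.
#' @param background A `background_model`, a [sequence_set()] of background
#'   windows, or a named character vector of protein sequences (a proteome,
#'   from which all width-matched subsequence windows are enumerated,
#'   restricted to `central_residue` centers when that filter is set). A
#'   background must always be supplied explicitly.
#' @param alpha Pre-correction significance level (default 0.001); the
#'   per-test threshold is `alpha / m` with
#'   `m = width * (20 + number of compound groups)` (Bonferroni).
#' @param min_support Minimum number of matching sequences a motif must have
#'   (default 20); smaller subsets are neither recursed nor emitted.
#' @param position_specific_background Test against per-position background
#'   frequencies (default `TRUE`) or pooled frequencies.
#' @param compound_groups `NULL` (off, the default), `"default"` for
#'   [default_compound_groups()], a path to a group file, or a named list.
#' @param central_residue Optional residue set; foreground windows whose
#'   central residue is not in the set are rejected before analysis. Unset by
#'   default: no central residue needs to be declared.
#' @param dedup_sequences Drop duplicate window strings before analysis
#'   (default `FALSE`).
#' @param tie_select `"branch"` (default) fixes all maximally enriched pairs
#'   simultaneously; `"greedy"` takes only the first, reproducing the
#'   order-dependent single-selection behaviour of older extractors (useful
#'   only as an ablation).
#' @return An object of class `motif_deconv`: list with `motifs` (each motif
#'   has `pairs`, `support`, `matched` window indices, `pattern`, `class`,
#'   and the per-pair enrichment `trail`), the retained `foreground`, the
#'   root `background`, the `config`, and ingestion counters.
#' @examples
#' demo <- generate_bias_demo(seed = 1)
#' fit <- motif_deconv(demo$foreground, demo$background)
#' fit
#' @export
motif_deconv <- function(foreground, background,
                         alpha = 0.001, min_support = 20L,
                         position_specific_background = TRUE,
                         compound_groups = NULL, central_residue = NULL,
                         dedup_sequences = FALSE,
                         tie_select = c("branch", "greedy")) {
  cl <- match.call()
  cfg <- new_engine_config(alpha, min_support, position_specific_background,
                           compound_groups, central_residue, dedup_sequences,
                           tie_select)
  if (is.character(foreground) && length(foreground) == 1L &&
      file.exists(foreground)) {
    foreground <- read_prealigned(foreground)
  }
  stopifnot(inherits(foreground, "sequence_set"))
  if (is.null(background)) {
    stop("an explicit background (model, window set, or proteome) is required")
  }
  if (inherits(background, "sequence_set")) {
    background <- build_background(background)
  } else if (is.character(background)) {
    background <- build_background(background, width = foreground$width,
                                   central_residue =
                                     if (length(cfg$central_residue) == 1L)
                                       cfg$central_residue)
  }
  stopifnot(inherits(background, "background_model"))
  if (foreground$width != background$width) {
    stop("foreground width ", foreground$width,
         " != background width ", background$width)
  }

  n_input <- length(foreground)
  n_rejected_central <- 0L
  if (!is.null(cfg$central_residue)) {
    center <- substr(foreground$windows, foreground$central_index,
                     foreground$central_index)
    keep <- center %in% cfg$central_residue
    n_rejected_central <- sum(!keep)
    if (!any(keep)) stop("no foreground windows with an allowed central residue")
    foreground <- foreground[keep]
  }
  n_duplicates <- 0L
  if (cfg$dedup_sequences) {
    keep <- !duplicated(foreground$windows)
    n_duplicates <- sum(!keep)
    foreground <- foreground[keep]
  }

  fmat <- seq_matrix(foreground)
  emitted <- list()
  recurse <- function(idx, bg, prefix, trail, emit) {
    res <- scan_matrix(fmat[idx, , drop = FALSE], bg, cfg)
    # offsets already fixed in the prefix are settled: every window in this
    # branch matches them, and under a pooled background their frequency
    # never saturates, so they must not be re-candidates
    res <- res[!(res$offset %in% prefix$offset), , drop = FALSE]
    sel <- select_maximal(res, cfg$tie_tol, cfg$min_support)
    if (nrow(sel) > 1L && cfg$tie_select == "greedy") {
      sel <- sel[1L, , drop = FALSE]
    }
    if (nrow(sel) == 0L) {
      if (emit && nrow(prefix) > 0L && length(idx) >= cfg$min_support) {
        emitted[[length(emitted) + 1L]] <<-
          assemble_motif(prefix, trail, idx, ncol(fmat))
      }
      return(invisible(NULL))
    }
    hits <- lapply(seq_len(nrow(sel)), function(i) {
      match_pair_matrix(fmat[idx, , drop = FALSE], sel$offset[i],
                        sel$members[i])
    })
    # merge co-matching pairs (identical matched sets) into a single branch:
    # they fix together and would otherwise spawn duplicate paths
    keys <- vapply(hits, function(h) paste(which(h), collapse = ","), "")
    for (key in unique(keys)) {
      rows <- which(keys == key)
      bidx <- idx[hits[[rows[1L]]]]
      if (length(bidx) < cfg$min_support) next
      branch_pairs <- canonical_pairs(sel[rows, , drop = FALSE],
                                      cfg$compound_groups)
      new_prefix <- rbind(prefix, branch_pairs)
      new_trail <- rbind(trail, sel[rows, , drop = FALSE])
      bg2 <- reduce_background(bg, branch_pairs, cfg$compound_groups)
      if (is.null(bg2)) {
        # background exhausted: terminate the branch, keep the motif
        emitted[[length(emitted) + 1L]] <<-
          assemble_motif(new_prefix, new_trail, bidx, ncol(fmat))
      } else {
        recurse(bidx, bg2, new_prefix, new_trail, emit = TRUE)
      }
    }
    ridx <- idx[!Reduce(`|`, hits)]
    if (length(ridx) >= cfg$min_support) {
      recurse(ridx, bg, prefix, trail, emit = FALSE)
    }
    invisible(NULL)
  }
  recurse(seq_len(nrow(fmat)), background, empty_pairs(),
          cbind(empty_pairs(),
                data.frame(k = integer(), n = integer(), p0 = numeric(),
                           log_p = numeric(), p = numeric(), m = integer(),
                           significant = logical())),
          emit = FALSE)

  motifs <- finalize_motifs(emitted)
  structure(
    list(motifs = motifs, foreground = foreground, background = background,
         config = cfg, n_input = n_input,
         n_rejected_central = n_rejected_central,
         n_duplicates_removed = n_duplicates, call = cl),
    class = "motif_deconv"
  )
}

assemble_motif <- function(pairs, trail, idx, width) {
  ord <- order(pairs$offset)
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  trail <- trail[ord, c("offset", "token", "is_group", "members", "k", "n",
                        "p0", "p", "log_p", "m", "significant"),
                 drop = FALSE]
  rownames(trail) <- NULL
  list(pairs = pairs, support = length(idx), matched = sort(idx),
       pattern = motif_pattern(pairs, width),
       class = classify_motif(pairs, width), trail = trail,
       width = as.integer(width))
}

motif_pattern <- function(pairs, width) {
  chars <- rep(".", width)
  col <- pairs$offset + (width - 1L) %/% 2L + 1L
  chars[col] <- ifelse(pairs$is_group, paste0("[", pairs$members, "]"),
                       pairs$token)
  paste(chars, collapse = "")
}

#' Complexity class of a motif
#'
#' Class I: the central position and at least one flanking position are
#' fixed. Class II: only the central position is fixed. Class III: flanking
#' positions are fixed but the central (modified) position is not.
#'
#' @param pairs Motif pair data frame (column `offset`), or a motif list.
#' @param width Window width (used only to validate offsets).
#' @return `"I"`, `"II"` or `"III"`.
#' @export
classify_motif <- function(pairs, width = NULL) {
  if (is.list(pairs) && !is.data.frame(pairs) && !is.null(pairs$pairs)) {
    pairs <- pairs$pairs
  }
  stopifnot(nrow(pairs) >= 1L)
  central <- any(pairs$offset == 0L)
  flank <- any(pairs$offset != 0L)
  if (central && flank) "I" else if (central) "II" else "III"
}

motif_key <- function(motif) {
  paste(sprintf("%s@%+d", motif$pairs$token, motif$pairs$offset),
        collapse = ";")
}

finalize_motifs <- function(motifs) {
  if (length(motifs) == 0L) return(list())
  keys <- vapply(motifs, motif_key, "")
  support <- vapply(motifs, `[[`, 0L, "support")
  # de-duplicate identical pair sets reached via different partition paths,
  # keeping the best-supported occurrence
  keep <- !logical(length(motifs))
  for (key in unique(keys)) {
    rows <- which(keys == key)
    if (length(rows) > 1L) {
      best <- rows[which.max(support[rows])]
      keep[setdiff(rows, best)] <- FALSE
    }
  }
  motifs <- motifs[keep]
  patterns <- vapply(motifs, `[[`, "", "pattern")
  support <- vapply(motifs, `[[`, 0L, "support")
  motifs[order(-support, patterns, method = "radix")]
}

#' Check reversal equivariance of motif extraction
#'
#' Runs extraction on (foreground, background) and on their character-reversed
#' counterparts, negates the offsets of the reversed-run motifs, and compares
#' the two motif sets exactly. A robust extractor returns `TRUE` on any input.
#'
#' @param foreground,background As in [motif_deconv()] (background as a model
#'   is re-built from reversed windows).
#' @param ... Further arguments passed to [motif_deconv()].
#' @return `TRUE` iff the reversed run reproduces the forward motifs after
#'   offset negation.
#' @export
reverse_equivalence_check <- function(foreground, background, ...) {
  if (inherits(background, "background_model")) {
    background <- sequence_set(apply_rows_paste(
      background$mat[, background$width:1L, drop = FALSE]))
    background_fwd <- reverse_windows(background)
  } else if (inherits(background, "sequence_set")) {
    background_fwd <- background
    background <- reverse_windows(background)
  } else {
    stop("background must be a background_model or sequence_set")
  }
  fwd <- motif_deconv(foreground, background_fwd, ...)
  rev <- motif_deconv(reverse_windows(foreground), background, ...)
  rev_keys <- sort(method = "radix", vapply(rev$motifs, function(m) {
    p <- m$pairs
    p$offset <- -p$offset
    p <- p[order(p$offset), , drop = FALSE]
    paste(sprintf("%s@%+d", p$token, p$offset), collapse = ";")
  }, ""))
  fwd_keys <- sort(vapply(fwd$motifs, motif_key, ""), method = "radix")
  identical(fwd_keys, rev_keys)
}
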
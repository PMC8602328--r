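# Reading and writing the package's external formats: pre-aligned window
# files, FASTA proteomes, site tables, motif tables.

#' Read pre-aligned sequence windows from a text file
#'
#' Each non-empty line is either `SEQ`, `LABEL<TAB>SEQ`, or
#' `LABEL<TAB>SEQ<TAB>INTENSITY`. All sequences must share one width.
#' Input is case-insensitive; windows are uppercased on read.
#'
#' @param path Path to a plain-text file.
#' @param expected_width Optional width to enforce (error on mismatch).
#' @return A [sequence_set()]; `sample` and `intensity` are set when the
#'   labelled dialects are used.
#' @examples
#' f <- tempfile()
#' writeLines(c("AAASAAA", "CCCSCCC"), f)
#' read_prealigned(f)$width
#' @export
read_prealigned <- function(path, expected_width = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- trimws(lines[keep])
  if (length(lines) == 0L) stop("no sequences in ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf > 3L)) {
    stop("too many fields at line ", which(nf > 3L)[1L], " of ", path)
  }
  seqs <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else p[1L], "")
  labels <- if (any(nf >= 2L)) {
    vapply(parts, function(p) if (length(p) >= 2L) p[1L] else NA_character_, "")
  }
  intensity <- if (any(nf == 3L)) {
    vapply(parts, function(p) {
      if (length(p) == 3L) as.numeric(p[3L]) else NA_real_
    }, 0)
  }
  widths <- nchar(seqs)
  ref <- if (is.null(expected_width)) widths[1L] else expected_width
  if (any(widths != ref)) {
    stop("inconsistent width at line ", which(widths != ref)[1L],
         ": expected ", ref, ", got ", widths[which(widths != ref)[1L]])
  }
  sequence_set(seqs, sample = labels, intensity = intensity)
}

#' Write a sequence set in the pre-aligned text dialect
#'
#' Inverse of [read_prealigned()]: emits `SEQ`, `LABEL<TAB>SEQ` or
#' `LABEL<TAB>SEQ<TAB>INTENSITY` lines depending on which fields are present.
#'
#' @param set A [sequence_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_prealigned <- function(set, path) {
  stopifnot(inherits(set, "sequence_set"))
  lines <- set$windows
  if (!is.null(set$sample)) {
    lines <- paste(set$sample, lines, sep = "\t")
    if (!is.null(set$intensity)) {
      lines <- paste(lines, format(set$intensity, trim = TRUE), sep = "\t")
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a proteome from FASTA
#'
#' @param path FASTA file of protein sequences.
#' @return Named character vector of uppercase sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_proteome <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[`, "", 1L)
  seqs
}

#' Write a proteome to FASTA
#'
#' @param proteome Named character vector of protein sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteome <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(proteome)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Read a modification site table
#'
#' Tab-separated with a header; required columns `accession`, `position`,
#' `modification`, optional `residue` (the residue the record claims is
#' modified, used to reject mismapped sites).
#'
#' @param path Path to the TSV.
#' @return Data frame of site records with 1-based `position`.
#' @export
read_site_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "position", "modification")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("site table is missing column(s): ", paste(miss, collapse = ", "))
  }
  df$position <- as.integer(df$position)
  if (any(df$position < 1L, na.rm = TRUE)) {
    stop("site positions must be 1-based (>= 1)")
  }
  if (!"residue" %in% names(df)) df$residue <- NA_character_
  df$residue <- toupper(df$residue)
  df[c("accession", "position", "modification", "residue")]
}

#' Extract a site-centered window from a protein sequence
#'
#' Returns the residue at `position` together with the flanking
#' `(width-1)/2` residues on each side; overhang beyond either terminus is
#' padded with `"-"`. When `expected_residue` is given and disagrees with the
#' protein residue at the site, the site is rejected (returns `NA`), which the
#' bulk extractor counts and reports separately from hard errors.
#'
#' @param protein_sequence Protein string.
#' @param position 1-based site position within the protein.
#' @param width Odd window width.
#' @param expected_residue Optional single residue the site claims to carry.
#' @return The window string, or `NA_character_` if the site is rejected on a
#'   residue mismatch.
#' @examples
#' extract_window("MKTAYIAKQRQISFVK", 8, 15)  # "MKTAYIAKQRQISFV"
#' extract_window("MKT", 1, 7)               # "---MKT-"
#' @export
extract_window <- function(protein_sequence, position, width,
                           expected_residue = NULL) {
  stopifnot_odd_width(width)
  protein_sequence <- toupper(protein_sequence)
  n <- nchar(protein_sequence)
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > n) {
    stop("site position ", position, " outside protein of length ", n)
  }
  actual <- substr(protein_sequence, position, position)
  if (!is.null(expected_residue) && !is.na(expected_residue) &&
      nzchar(expected_residue) && toupper(expected_residue) != actual) {
    return(NA_character_)
  }
  h <- (width - 1L) %/% 2L
  lo <- position - h
  hi <- position + h
  core <- substr(protein_sequence, max(1L, lo), min(n, hi))
  paste0(strrep(GAP, max(0L, 1L - lo)), core, strrep(GAP, max(0L, hi - n)))
}

#' Extract windows for a table of sites from a proteome
#'
#' Maps each site's accession to the proteome (first exact name match),
#' de-duplicates on (accession, position, modification), extracts windows and
#' tallies rejections.
#'
#' @param proteome Named character vector of protein sequences.
#' @param sites Site data frame as returned by [read_site_table()].
#' @param width Odd window width.
#' @param dedup De-duplicate sites before extraction (default `TRUE`).
#' @return List with `set` (a [sequence_set()] whose `source` records the
#'   originating sites), `n_unmapped` (accessions absent from the proteome),
#'   `n_out_of_range` and `n_residue_mismatch` rejection counts.
#' @export
extract_windows <- function(proteome, sites, width, dedup = TRUE) {
  stopifnot_odd_width(width)
  if (dedup) sites <- dedup_sites(sites)
  idx <- match(sites$accession, names(proteome))
  unmapped <- is.na(idx)
  windows <- rep(NA_character_, nrow(sites))
  oor <- logical(nrow(sites))
  for (i in which(!unmapped)) {
    prot <- proteome[[idx[i]]]
    if (sites$position[i] > nchar(prot) || sites$position[i] < 1L) {
      oor[i] <- TRUE
      next
    }
    windows[i] <- extract_window(prot, sites$position[i], width,
                                 expected_residue = sites$residue[i])
  }
  mism <- !unmapped & !oor & is.na(windows)
  ok <- !is.na(windows)
  if (!any(ok)) stop("no sites could be mapped to windows")
  set <- sequence_set(windows[ok],
                      sample = if ("sample" %in% names(sites))
                        sites$sample[ok],
                      source = sites[ok, c("accession", "position",
                                           "modification")])
  list(set = set,
       n_unmapped = sum(unmapped),
       n_out_of_range = sum(oor),
       n_residue_mismatch = sum(mism))
}

#' De-duplicate site records
#'
#' Collapses exact duplicates on (accession, position, modification); records
#' that differ in any of the three are all retained.
#'
#' @param sites Site data frame.
#' @return The de-duplicated data frame (idempotent).
#' @export
dedup_sites <- function(sites) {
  if (nrow(sites) == 0L) return(sites)
  key <- paste(sites$accession, sites$position, sites$modification,
               sep = "\r")
  sites[!duplicated(key), , drop = FALSE]
}

#' Drop modifications with too few sites
#'
#' @param sites_by_modification Named list (one element per modification) of
#'   site tables or window sets.
#' @param min_n Minimum number of records a modification must have to be
#'   retained (default 50).
#' @return The filtered list, elements unchanged.
#' @examples
#' filter_min_occurrence(list(a = 1:49, b = 1:50), min_n = 50)
#' @export
filter_min_occurrence <- function(sites_by_modification, min_n = 50L) {
  stopifnot(min_n >= 1L)
  n <- vapply(sites_by_modification, NROW, 0L)
  sites_by_modification[n >= min_n]
}

#' Write a motif table as TSV
#'
#' One row per motif with columns `pattern`, `fixed_pairs` (semicolon-joined
#' `token@offset`, group members spelled out as `name=MEMBERS`), `support`,
#' `class`, `pair_pvalues` (semicolon-joined, same order as `fixed_pairs`) and
#' `n_matched`. Rows are ordered by descending support, then pattern.
#'
#' @param motifs List of motifs (elements of a [motif_deconv()] fit's
#'   `motifs`) or a `motif_deconv` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_table <- function(motifs, path) {
  if (inherits(motifs, "motif_deconv")) motifs <- motifs$motifs
  df <- motif_table(motifs)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

motif_table <- function(motifs) {
  if (length(motifs) == 0L) {
    return(data.frame(pattern = character(), fixed_pairs = character(),
                      support = integer(), class = character(),
                      pair_pvalues = character(), n_matched = integer(),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(
    pattern = vapply(motifs, `[[`, "", "pattern"),
    fixed_pairs = vapply(motifs, function(m) {
      p <- m$pairs
      tok <- ifelse(p$is_group, paste0(p$token, "=", p$members), p$token)
      paste(sprintf("%s@%+d", tok, p$offset), collapse = ";")
    }, ""),
    support = vapply(motifs, `[[`, 0L, "support"),
    class = vapply(motifs, `[[`, "", "class"),
    pair_pvalues = vapply(motifs, function(m) {
      paste(formatC(m$trail$p, digits = 17, format = "g"), collapse = ";")
    }, ""),
    n_matched = vapply(motifs, function(m) {
      if (length(m$matched)) length(m$matched) else m$n_matched %||% 0L
    }, 0L),
    stringsAsFactors = FALSE
  )
  df[order(-df$support, df$pattern, method = "radix"), , drop = FALSE]
}

#' Read a motif table written by [write_motif_table()]
#'
#' @param path Path to the TSV.
#' @param width Window width the motifs refer to.
#' @return List of motifs (pairs, support, class, pattern, per-pair p-values);
#'   `matched` indices are not stored in the table and come back empty.
#' @export
read_motif_table <- function(path, width) {
  stopifnot_odd_width(width)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(pattern = "character",
                                         fixed_pairs = "character",
                                         class = "character",
                                         pair_pvalues = "character"))
  lapply(seq_len(nrow(df)), function(i) {
    toks <- strsplit(df$fixed_pairs[i], ";", fixed = TRUE)[[1]]
    parts <- regmatches(toks, regexec("^([^@]+)@([+-]\\d+)$", toks))
    token <- vapply(parts, `[`, "", 2L)
    offset <- as.integer(vapply(parts, `[`, "", 3L))
    is_group <- grepl("=", token, fixed = TRUE)
    members <- ifelse(is_group, sub("^[^=]+=", "", token), token)
    token <- sub("=.*$", "", token)
    pairs <- data.frame(offset = offset, token = token, is_group = is_group,
                        members = members, stringsAsFactors = FALSE)
    pairs <- pairs[order(pairs$offset), , drop = FALSE]
    ps <- as.numeric(strsplit(df$pair_pvalues[i], ";", fixed = TRUE)[[1]])
    list(pairs = pairs, support = df$support[i], matched = integer(),
         n_matched = df$n_matched[i],
         pattern = df$pattern[i], class = df$class[i],
         trail = data.frame(offset = offset, token = token, p = ps,
                            stringsAsFactors = FALSE),
         width = as.integer(width))
  })
}
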
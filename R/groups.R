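# Compound residue groups: sets of residues sharing a physicochemical
# property, tested for positional enrichment as single tokens.

#' Default compound residue groups
#'
#' A standard physicochemical partition of the 20 residues: acidic, basic,
#' polar-uncharged, nonpolar-aliphatic, aromatic and tiny. Enabled by passing
#' `compound_groups = "default"` (or this list) to [motif_deconv()];
#' replaceable by a custom group file via [read_compound_groups()].
#'
#' @return Named list of character vectors of member residues.
#' @export
default_compound_groups <- function() {
  list(
    acidic    = c("D", "E"),
    basic     = c("K", "R", "H"),
    polar     = c("S", "T", "N", "Q"),
    aliphatic = c("A", "V", "L", "I", "M"),
    aromatic  = c("F", "W", "Y"),
    tiny      = c("G", "P", "C")
  )
}

#' Read compound residue groups from a text file
#'
#' One group per line, `name:RESIDUES` (e.g. `acidic:DE`). Group names must
#' not collide with single-residue tokens and groups need at least two
#' distinct member residues.
#'
#' @param path Path to the group definition file.
#' @return Named list of character vectors, as [default_compound_groups()].
#' @export
read_compound_groups <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, ":", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) stop("malformed group definition at line ", bad[1L])
  groups <- lapply(parts, function(p) {
    unique(strsplit(toupper(trimws(p[2L])), "", fixed = TRUE)[[1]])
  })
  names(groups) <- vapply(parts, function(p) trimws(p[1L]), "")
  validate_groups(groups)
}

validate_groups <- function(groups) {
  if (is.null(groups)) return(NULL)
  stopifnot(is.list(groups), !is.null(names(groups)), all(nzchar(names(groups))))
  if (anyDuplicated(names(groups))) stop("duplicated group names")
  for (nm in names(groups)) {
    g <- unique(toupper(groups[[nm]]))
    if (nchar(nm) == 1L && nm %in% AA20) {
      stop("group name '", nm, "' collides with a residue token")
    }
    if (length(g) < 2L) stop("group '", nm, "' needs at least 2 residues")
    if (!all(g %in% AA20)) {
      stop("group '", nm, "' contains non-standard residues")
    }
    groups[[nm]] <- g
  }
  groups[order(names(groups), method = "radix")]
}
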
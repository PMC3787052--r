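#' Built-in NCS-1 segment registry
#'
#' Named residue ranges (author numbering, inclusive) for the NCS-1
#' secondary-structure elements: helices H1-H9, strands B1-B6, loops L1-L3,
#' the protein core `PC` (residues 11-174, the span between H1 and H9 used
#' for all alignments) and the hinge loop `HL` linking the N- and
#' C-terminal domains. The C-terminal tail is listed twice because two
#' conventions for it exist in the literature: `L3` (175-187) and the
#' alternative `L3_METHODS` (176-190); neither is privileged. `ALL` selects
#' every residue.
#'
#' @return A tibble with columns `segment`, `first`, `last`.
#' @export
ncs1_segments <- function() {
  tibble(
    segment = c(
      "H1", "H2", "H3", "H4", "H5", "H6", "H7", "H8", "H9",
      "B1", "B2", "B3", "B4", "B5", "B6",
      "L1", "L2", "L3", "L3_METHODS", "PC", "HL"
    ),
    first = c(
      11L, 24L, 45L, 62L, 82L, 98L, 118L, 146L, 166L,
      42L, 58L, 79L, 115L, 136L, 163L,
      56L, 133L, 175L, 176L, 11L, 93L
    ),
    last = c(
      18L, 34L, 54L, 72L, 93L, 108L, 132L, 155L, 174L,
      44L, 60L, 81L, 117L, 138L, 165L,
      61L, 145L, 187L, 190L, 174L, 98L
    )
  )
}

#' Build a custom segment table
#'
#' @param ... Named integer vectors of length 2, e.g. `core = c(1, 25)`.
#' @return A tibble with columns `segment`, `first`, `last`.
#' @export
segment_table <- function(...) {
  entries <- list(...)
  if (length(entries) == 0) abort("segment_table() needs at least one range")
  stopifnot(!is.null(names(entries)), all(names(entries) != ""))
  out <- tibble(
    segment = names(entries),
    first = as.integer(vapply(entries, `[`, numeric(1), 1)),
    last = as.integer(vapply(entries, `[`, numeric(1), 2))
  )
  if (any(out$first > out$last)) abort("segment ranges must have first <= last")
  out
}

.backbone_names <- c("N", "CA", "C", "O")

#' Select atoms by segment and atom class
#'
#' Restricts a structure to the residues falling inside the union of the
#' named segment ranges and to one atom class, returning atom indices. The
#' backbone set defaults to `N, CA, C, O` and may be narrowed (e.g.
#' `c("N","CA","C")` or `"CA"`) to match other RMSD conventions.
#'
#' @param structure A structure tibble.
#' @param segments Character vector of segment names present in `table`.
#' @param atom_class One of `"backbone"`, `"heavy"`, `"all"`, `"protons"`.
#' @param table Segment table (default [ncs1_segments()]).
#' @param backbone Atom names constituting the backbone.
#' @return Integer atom indices into `structure`, with attribute
#'   `provenance` recording the selection expression. An empty selection is
#'   an error, never a silent empty set.
#' @export
select_atoms <- function(structure, segments = "ALL",
                         atom_class = c("backbone", "heavy", "all", "protons"),
                         table = ncs1_segments(),
                         backbone = .backbone_names) {
  atom_class <- match.arg(atom_class)
  keep <- rep(FALSE, nrow(structure))
  for (seg in segments) {
    if (identical(seg, "ALL")) {
      keep <- keep | TRUE
      next
    }
    row <- table[table$segment == seg, ]
    if (nrow(row) == 0) {
      abort(sprintf(
        "unknown segment '%s' (known: %s)",
        seg, paste(table$segment, collapse = ", ")
      ))
    }
    keep <- keep | (structure$resid >= row$first[1] &
      structure$resid <= row$last[1])
  }
  cls <- switch(atom_class,
    backbone = structure$name %in% backbone,
    heavy = structure$element != "H",
    protons = structure$element == "H",
    all = rep(TRUE, nrow(structure))
  )
  idx <- which(keep & cls)
  if (length(idx) == 0) {
    abort(sprintf(
      "selection '%s' / %s matches no atoms",
      paste(segments, collapse = ","), atom_class
    ))
  }
  attr(idx, "provenance") <- sprintf(
    "segments=%s; atom_class=%s", paste(segments, collapse = ","), atom_class
  )
  idx
}
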
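#' Compare the crystal and solution structures of NCS-1
#'
#' Computes the protein-core backbone RMSD and the partial RMSDs of every
#' registry segment between chain B of the crystal structure (PDB 1G8I)
#' and the first model of the NMR ensemble (PDB 2LCP), after a
#' least-squares fit over the backbone of residues 11-174. The two PDB
#' files must be supplied by the user (they are not redistributed with the
#' package); the published comparison gives a core RMSD of about 4.4 A,
#' with partial values around 6.4 A for H1, 4.0 A for H9 and 3.2 A for L1.
#'
#' @param xr_path Path to the crystal-structure PDB file (1G8I).
#' @param nmr_path Path to the NMR-ensemble PDB file (2LCP).
#' @param chain Crystal chain to use (default `"B"`).
#' @param model NMR model to use (default 1).
#' @param backbone Backbone atom-name convention (see [select_atoms()]).
#' @param segments Segment names to report in addition to `PC`.
#' @return Tibble with columns `segment` and `rmsd` (Angstrom); the first
#'   row is the core (`PC`) fit-equals-measure value.
#' @export
compare_deposited <- function(xr_path, nmr_path, chain = "B", model = 1,
                              backbone = .backbone_names,
                              segments = c(
                                "H1", "H2", "H3", "H4", "H5", "H6", "H7",
                                "H8", "H9", "B1", "B2", "B3", "B4", "B5",
                                "B6", "L1", "L2", "L3"
                              )) {
  xr <- read_structure(xr_path, chain = chain, label = "crystal")
  nmr <- read_structure(nmr_path, model_index = model, label = "solution")
  vals <- vapply(c("PC", segments), function(seg) {
    rmsd_partial(nmr, xr, fit = "PC", measure = seg, backbone = backbone)
  }, numeric(1))
  tibble(segment = c("PC", segments), rmsd = unname(vals))
}

# location of user-supplied deposited PDB files; errors when absent so the
# downstream computation never runs on missing inputs silently
deposited_path <- function(id, dir = getOption("ncstraj.pdb_dir", NULL)) {
  candidates <- c(
    if (!is.null(dir)) file.path(dir, paste0(id, ".pdb")),
    system.file("extdata", paste0(id, ".pdb"), package = "ncstraj"),
    file.path("inst", "extdata", paste0(id, ".pdb"))
  )
  candidates <- candidates[nzchar(candidates)]
  hit <- candidates[file.exists(candidates)]
  if (length(hit) == 0) {
    abort(sprintf(
      paste0(
        "deposited structure %s.pdb not available; download it from the ",
        "PDB and point options(ncstraj.pdb_dir=) at its directory"
      ), id
    ))
  }
  hit[1]
}
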
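#' Pairwise RMSD matrix of trajectory frames
#'
#' Superposes every sampled frame pair over the fit selection (Kabsch) and
#' records the post-fit RMSD, yielding the symmetric distance matrix used
#' for conformational clustering.
#'
#' @param traj An `md_trajectory`.
#' @param fit Segment names for the fitted atom selection.
#' @param stride,window Sampling controls (see [compute_iem()]).
#' @inheritParams rmsd_partial
#' @return Symmetric numeric matrix (Angstrom) with zero diagonal;
#'   attributes `frames` (original frame indices) and `times` (ps).
#' @export
rmsd_matrix <- function(traj, fit = "PC", stride = NULL, window = NULL,
                        atom_class = "backbone", table = ncs1_segments(),
                        backbone = .backbone_names) {
  idx <- sample_frames(traj, stride = stride, window = window)
  if (length(idx) < 2) abort("need at least two sampled frames")
  sel <- select_atoms(traj$topology, fit,
    atom_class = atom_class,
    table = table, backbone = backbone
  )
  n <- length(idx)
  m <- matrix(0, n, n)
  xs <- lapply(idx, function(f) traj$frames[[f]][sel, , drop = FALSE])
  for (a in seq_len(n - 1)) {
    for (b in seq(a + 1, n)) {
      r <- tryCatch(kabsch(xs[[a]], xs[[b]])$rmsd, error = function(e) {
        abort(sprintf(
          "frames %d/%d: %s", idx[a], idx[b], conditionMessage(e)
        ))
      })
      m[a, b] <- r
      m[b, a] <- r
    }
  }
  attr(m, "frames") <- idx
  attr(m, "times") <- (idx - 1) * traj$dt
  m
}

#' Hierarchical conformational clustering of frames
#'
#' Complete-linkage hierarchical clustering of the frame-frame RMSD matrix,
#' cut at a fixed height. Complete linkage certifies that every pair of
#' frames inside a cluster is within the cutoff of each other, which is
#' what makes a 2 A cut a statement about conformational state identity.
#' Cluster ids are ordered by population (descending), ties broken by the
#' smallest member frame index, so cluster 1 is always the most populated.
#'
#' @param matrix Symmetric RMSD matrix from [rmsd_matrix()].
#' @param cutoff Cut height, Angstrom (default 2).
#' @param linkage Linkage criterion; only `"complete"` is supported.
#' @return A `cluster_assignment`: list with `labels` (per sampled frame),
#'   `populations`, `representatives` (medoid frame positions), `cutoff`,
#'   `linkage` and, when present on the matrix, the original `frames` and
#'   `times`.
#' @export
cluster_frames <- function(matrix, cutoff = 2, linkage = "complete") {
  linkage <- match.arg(linkage, "complete")
  if (any(is.na(matrix))) abort("RMSD matrix contains NA")
  n <- nrow(matrix)
  raw <- if (all(matrix[upper.tri(matrix)] <= cutoff)) {
    # hclust needs >= 2 observations with positive heights; the trivial
    # one-cluster case is resolved directly
    rep(1L, n)
  } else {
    cutree(hclust(as.dist(matrix), method = linkage), h = cutoff)
  }
  # relabel: population descending, ties by smallest member frame index
  first_member <- vapply(
    split(seq_len(n), raw), min, numeric(1)
  )
  pop <- vapply(split(seq_len(n), raw), length, numeric(1))
  ord <- order(-pop, first_member)
  relabel <- integer(length(ord))
  relabel[as.integer(names(pop))[ord]] <- seq_along(ord)
  labels <- relabel[raw]
  pops <- as.integer(table(labels))
  reps <- vapply(seq_along(pops), function(c) {
    representative(matrix, which(labels == c))
  }, integer(1))
  structure(
    list(
      labels = labels, populations = pops, representatives = reps,
      cutoff = cutoff, linkage = linkage,
      frames = attr(matrix, "frames"), times = attr(matrix, "times")
    ),
    class = "cluster_assignment"
  )
}

#' Medoid representative of a cluster
#'
#' The member minimising the summed RMSD to all other members — the usual
#' operational meaning of "most representative structure". Ties go to the
#' smallest frame index.
#'
#' @param matrix Symmetric distance matrix.
#' @param members Integer indices (rows of `matrix`) of the cluster.
#' @return The representative member index (into `matrix`).
#' @export
representative <- function(matrix, members) {
  if (length(members) == 0) abort("cluster has no members")
  if (length(members) == 1) {
    return(as.integer(members))
  }
  sums <- rowSums(matrix[members, members, drop = FALSE])
  as.integer(members[which.min(sums)]) # which.min takes the first minimum
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "<cluster_assignment> %d frames -> %d cluster(s) at %.2f A (%s linkage)\n",
    length(x$labels), length(x$populations), x$cutoff, x$linkage
  ))
  cat(
    "  populations:", paste(x$populations, collapse = ", "), "\n"
  )
  invisible(x)
}
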
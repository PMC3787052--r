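# shared fixtures and independent oracles for the test suite

# hand-formatted PDB ATOM/HETATM line (fixed columns) for parser edge cases
pdb_line <- function(type = "ATOM", serial, name, resname, resid,
                     chain = "A", x, y, z, occ = 1, b = 0, alt = "",
                     element = substr(name, 1, 1)) {
  sprintf(
    "%-6s%5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    type, serial, name, alt, resname, chain, resid, x, y, z, occ, b, element
  )
}

write_pdb_text <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# minimal two-residue dipeptide with ideal-ish backbone coordinates
toy_dipeptide <- function() {
  build_helix(c("ALA", "GLY", "ALA", "GLY"))
}

# uniform nonbonded parameter table covering every atom type of a structure
uniform_params <- function(structure, charge = 0, epsilon = 0.05,
                           rmin_half = 2.0) {
  tt <- unique(data.frame(residue = structure$resname, atom = structure$name))
  tibble::tibble(
    residue = tt$residue, atom = tt$atom,
    charge = charge, epsilon = epsilon, rmin_half = rmin_half
  )
}

# independent quaternion (Horn) superposition oracle: optimal RMSD from the
# largest eigenvalue of the 4x4 key matrix; no SVD, proper rotations only
horn_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(Pc, Qc)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  lam <- max(eigen(N, symmetric = TRUE)$values)
  sqrt(max(sum(Pc^2) + sum(Qc^2) - 2 * lam, 0) / nrow(P))
}

# independent naive double-loop residue-pair energy: every atom pair of the
# two residues, scalar arithmetic only, own bond-graph BFS for exclusions
naive_pair_energy <- function(structure, params, res_i, res_j,
                              exclude_bonded = 3) {
  xyz <- cbind(structure$x, structure$y, structure$z)
  key <- paste(params$residue, params$atom)
  prow <- function(k) {
    params[match(paste(structure$resname[k], structure$name[k]), key), ]
  }
  # own bond perception + breadth-first bond distance
  n <- nrow(structure)
  adj <- vector("list", n)
  for (a in seq_len(n - 1)) {
    for (b in seq(a + 1, n)) {
      d <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
      lim <- if (structure$element[a] == "H" ||
        structure$element[b] == "H") 1.3 else 1.9
      if (d < lim) {
        adj[[a]] <- c(adj[[a]], b)
        adj[[b]] <- c(adj[[b]], a)
      }
    }
  }
  bond_dist <- function(a, b, maxd) {
    seen <- a
    frontier <- a
    for (k in seq_len(maxd)) {
      frontier <- setdiff(unique(unlist(adj[frontier])), seen)
      if (b %in% frontier) return(k)
      if (length(frontier) == 0) return(Inf)
      seen <- c(seen, frontier)
    }
    Inf
  }
  ia <- which(structure$resid == res_i)
  ib <- which(structure$resid == res_j)
  total <- 0
  for (a in ia) {
    for (b in ib) {
      if (exclude_bonded > 0 && bond_dist(a, b, exclude_bonded) <= exclude_bonded) next
      pa <- prow(a); pb <- prow(b)
      r <- sqrt(sum((xyz[a, ] - xyz[b, ])^2))
      s <- if (r <= 10) {
        1
      } else if (r >= 12) {
        0
      } else {
        (144 - r^2)^2 * (144 + 2 * r^2 - 300) / (144 - 100)^3
      }
      rmin <- pa$rmin_half + pb$rmin_half
      e <- 332.0636 * pa$charge * pb$charge / r +
        sqrt(pa$epsilon * pb$epsilon) * ((rmin / r)^12 - 2 * (rmin / r)^6)
      total <- total + s * e
    }
  }
  total
}
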
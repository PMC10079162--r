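# Solvent-accessible surface area by Shrake-Rupley sphere sampling with a
# deterministic golden-spiral point set, and per-residue relative exposure
# against extended Gly-X-Gly reference areas.

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice)
golden_spiral_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = cos(theta) * sin(phi),
        y = sin(theta) * sin(phi),
        z = cos(phi))
}

# Per-atom accessible area for a set of heavy atoms.
# xyz: n x 3 matrix; radii: vdW radii; returns numeric vector (A^2)
atom_sasa <- function(xyz, radii, probe = 1.4, sphere_points = 256L) {
  n <- nrow(xyz)
  pts <- golden_spiral_points(sphere_points)
  r_ext <- radii + probe
  out <- numeric(n)
  # neighbour search: atoms can only occlude within r_i + r_j + 2*probe
  max_r <- max(r_ext)
  for (i in seq_len(n)) {
    d2 <- (xyz[, 1] - xyz[i, 1])^2 + (xyz[, 2] - xyz[i, 2])^2 +
      (xyz[, 3] - xyz[i, 3])^2
    nb <- which(d2 > 0 & sqrt(d2) < r_ext[i] + max_r)
    nb <- nb[sqrt(d2[nb]) < r_ext[i] + r_ext[nb]]
    surf <- pts * r_ext[i]
    surf <- sweep(surf, 2, xyz[i, ], "+")
    acc <- rep(TRUE, sphere_points)
    for (j in nb) {
      dj2 <- (surf[, 1] - xyz[j, 1])^2 + (surf[, 2] - xyz[j, 2])^2 +
        (surf[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > r_ext[j]^2
      if (!any(acc)) break
    }
    out[i] <- 4 * pi * r_ext[i]^2 * sum(acc) / sphere_points
  }
  out
}

#' Relative solvent exposure per residue
#'
#' Sums heavy-atom accessible areas per residue (Shrake-Rupley sampling with
#' a deterministic golden-spiral point set) and divides by the tabulated
#' maximum area of the residue type in an extended Gly-X-Gly tripeptide.
#' Values are clipped to `[0, 1]`. Residues of unknown type use the mean
#' reference area (with a warning).
#'
#' @param structure a `protein_structure`
#' @param probe probe radius in Angstrom
#' @param sphere_points number of sampling points per atom
#' @return named numeric vector of exposures, one per residue key
#' @export
relative_exposure <- function(structure, probe = 1.4, sphere_points = 256L) {
  atoms <- structure$atoms
  radii <- ELEMENT_RADII[atoms$elesy]
  radii[is.na(radii)] <- ELEMENT_RADIUS_DEFAULT
  area <- atom_sasa(as.matrix(atoms[, c("x", "y", "z")]), radii,
                    probe = probe, sphere_points = as.integer(sphere_points))
  res_area <- tapply(area, atoms$key, sum)
  keys <- unique(atoms$key)
  res_area <- res_area[keys]
  aa <- atoms$aa[match(keys, atoms$key)]
  ref <- AA_MAX_ASA[aa]
  if (anyNA(ref)) {
    warning("unknown residue type(s); using mean reference area")
    ref[is.na(ref)] <- mean(AA_MAX_ASA)
  }
  expo <- pmin(pmax(as.numeric(res_area) / as.numeric(ref), 0), 1)
  stats::setNames(expo, keys)
}
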
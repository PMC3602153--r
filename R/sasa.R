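#' Deterministic unit-sphere point set (golden-section spiral)
#'
#' @param n Number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Shrake-Rupley solvent-accessible surface area of an atom set
#'
#' Rolls a probe sphere over van der Waals spheres using a deterministic
#' golden-spiral point set. Returns per-atom areas and, optionally, the
#' exposed surface points themselves (used for surface-field sampling).
#'
#' @param atoms Data frame with columns `element`, `x`, `y`, `z`.
#' @param probe_radius Probe radius in Angstroms (water: 1.4).
#' @param n_points Sphere points per atom.
#' @param radii Named vdW radius table by element; defaults to [VDW_RADII].
#' @param keep_points If `TRUE`, also return exposed point coordinates with
#'   their owning atom index.
#' @return List with `atom_area` (numeric, Angstrom^2 per atom) and, when
#'   requested, `points` (data frame `x`, `y`, `z`, `atom`).
#' @export
shrake_rupley <- function(atoms, probe_radius = 1.4, n_points = 960,
                          radii = VDW_RADII, keep_points = FALSE) {
  stopifnot(probe_radius > 0, n_points >= 1)
  unknown <- setdiff(unique(atoms$element), names(radii))
  if (length(unknown) > 0) {
    stop("unknown element(s) with no vdW radius: ",
         paste(unknown, collapse = ", "))
  }
  n <- nrow(atoms)
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r_ext <- radii[atoms$element] + probe_radius
  sp <- sphere_points(n_points)

  area <- numeric(n)
  pts_list <- if (keep_points) vector("list", n) else NULL

  if (n > 1) {
    d2 <- sqdist_xyz(xyz, xyz)
  }

  for (i in seq_len(n)) {
    pts <- sweep(sp * r_ext[i], 2, xyz[i, ], "+")
    if (n > 1) {
      nb <- which(d2[i, ] < (r_ext[i] + r_ext)^2)
      nb <- setdiff(nb, i)
    } else nb <- integer(0)
    if (length(nb) > 0) {
      pd2 <- sqdist_xyz(pts, xyz[nb, , drop = FALSE])
      occluded <- rowSums(pd2 < matrix(r_ext[nb]^2, nrow = n_points,
                                       ncol = length(nb), byrow = TRUE)) > 0
    } else {
      occluded <- rep(FALSE, n_points)
    }
    frac <- mean(!occluded)
    area[i] <- 4 * pi * r_ext[i]^2 * frac
    if (keep_points && any(!occluded)) {
      pts_list[[i]] <- cbind(pts[!occluded, , drop = FALSE], atom = i)
    }
  }

  out <- list(atom_area = area)
  if (keep_points) {
    pts <- do.call(rbind, pts_list)
    out$points <- data.frame(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                             atom = as.integer(pts[, 4]))
  }
  out
}

#' Per-residue solvent-accessible area and relative accessibility
#'
#' @param structure A `DomainStructure`.
#' @param probe_radius Probe radius in Angstroms.
#' @param n_points Shrake-Rupley sphere points per atom.
#' @param radii vdW radius table.
#' @return Data frame with `chain`, `residue_index`, `residue_name`, `aa`,
#'   `area` (Angstrom^2) and `rel_acc` (fraction of the Gly-X-Gly reference
#'   maximum, uncapped); attribute `total` holds the summed area.
#' @export
compute_sasa <- function(structure, probe_radius = 1.4, n_points = 960,
                         radii = VDW_RADII) {
  at <- structure$atoms
  sr <- shrake_rupley(at, probe_radius, n_points, radii)
  key <- paste(at$chain, at$residue_index)
  per_res <- tapply(sr$atom_area, key, sum)
  first <- at[!duplicated(key), , drop = FALSE]
  rk <- paste(first$chain, first$residue_index)
  res <- data.frame(
    chain = first$chain,
    residue_index = first$residue_index,
    residue_name = first$residue_name,
    aa = first$aa,
    area = as.numeric(per_res[rk]),
    stringsAsFactors = FALSE
  )
  res$rel_acc <- res$area / MAX_ASA[res$aa]
  res <- res[order(res$chain, res$residue_index), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "total") <- sum(res$area)
  res
}

# Exposed molecular-surface points with owning residue and chain.
surface_points <- function(structure, probe_radius = 1.4, n_points = 960,
                           radii = VDW_RADII) {
  at <- structure$atoms
  sr <- shrake_rupley(at, probe_radius, n_points, radii, keep_points = TRUE)
  pts <- sr$points
  pts$chain <- at$chain[pts$atom]
  pts$residue_index <- at$residue_index[pts$atom]
  pts$aa <- at$aa[pts$atom]
  pts
}
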
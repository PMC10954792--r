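# 3D lattice geometry: site indexing, Moore neighborhoods, boundary
# vasculature, and the uniform region partition used by the region-averaged
# ("global") kinetics.

# The 26 Moore offsets, fixed column order, with Euclidean distances in site
# lengths (1, sqrt(2), sqrt(3)).
moore_offsets <- function() {
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(off != 0) > 0, , drop = FALSE]
  rownames(off) <- NULL
  off
}

#' Build lattice geometry tables
#'
#' Precomputes site coordinates, the 26-column Moore neighbor index table
#' (`NA` where a neighbor falls outside the lattice), neighbor distances, and
#' the perivascular (boundary) site set. Blood vessels sit on the lattice
#' border; every site with at least one coordinate on the border is
#' perivascular and is where recruited CTLs and systemic drugs enter the TME.
#'
#' @param dims integer triple, sites per axis (each >= 3).
#' @return list with `dims`, `nsite`, coordinate vectors `x`,`y`,`z`,
#'   neighbor table `nb` (nsite x 26), `nb_dist` (length 26), `peri`
#'   (perivascular site indices).
#' @export
make_lattice <- function(dims) {
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3, all(dims >= 3))
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  nsite <- nx * ny * nz
  xs <- rep_len(seq_len(nx), nsite)
  ys <- rep(rep(seq_len(ny), each = nx), times = nz)
  zs <- rep(seq_len(nz), each = nx * ny)
  off <- moore_offsets()
  nb <- matrix(NA_integer_, nrow = nsite, ncol = nrow(off))
  for (k in seq_len(nrow(off))) {
    x2 <- xs + off[k, 1]; y2 <- ys + off[k, 2]; z2 <- zs + off[k, 3]
    ok <- x2 >= 1L & x2 <= nx & y2 >= 1L & y2 <= ny & z2 >= 1L & z2 <= nz
    id <- x2 + (y2 - 1L) * nx + (z2 - 1L) * nx * ny
    id[!ok] <- NA_integer_
    nb[, k] <- id
  }
  peri <- which(xs == 1L | xs == nx | ys == 1L | ys == ny | zs == 1L | zs == nz)
  list(dims = dims, nsite = nsite, x = xs, y = ys, z = zs,
       nb = nb, nb_dist = sqrt(rowSums(off^2)), peri = peri)
}

#' @keywords internal
site_index <- function(dims, x, y, z) {
  as.integer(x + (y - 1L) * dims[1] + (z - 1L) * dims[1] * dims[2])
}

#' Moore neighborhood of a lattice site
#'
#' Returns the up-to-26 in-bounds neighbors of a site together with their
#' Euclidean distances (in site lengths): 1 for face neighbors, sqrt(2) for
#' edge-diagonal, sqrt(3) for body-diagonal neighbors. Interior sites have 26
#' neighbors; corners have 7.
#'
#' @param site integer triple (x, y, z), 1-based.
#' @param dims lattice dimensions, integer triple.
#' @return data.frame with columns `x`, `y`, `z`, `distance`.
#' @export
moore_neighbors <- function(site, dims) {
  site <- as.integer(site); dims <- as.integer(dims)
  stopifnot(length(site) == 3, length(dims) == 3)
  if (any(site < 1L) || any(site > dims))
    stop("site ", paste(site, collapse = ","), " is outside the lattice")
  off <- moore_offsets()
  x <- site[1] + off[, 1]; y <- site[2] + off[, 2]; z <- site[3] + off[, 3]
  d <- sqrt(rowSums(off^2))
  ok <- x >= 1L & x <= dims[1] & y >= 1L & y <= dims[2] & z >= 1L & z <= dims[3]
  data.frame(x = x[ok], y = y[ok], z = z[ok], distance = d[ok])
}

# Uniform partition of the lattice into regions_per_axis^3 cubic blocks.
# Returns per-site region ids, the 6-neighbor region adjacency used for the
# region-graph Laplacian, and the boundary-region flags that receive vascular
# drug influx.
#' @keywords internal
make_regions <- function(lat, regions_per_axis) {
  rpa <- as.integer(regions_per_axis)
  dims <- lat$dims
  if (any(dims %% rpa != 0))
    stop("lattice dims must be divisible by regions_per_axis")
  block <- dims %/% rpa
  rx <- (lat$x - 1L) %/% block[1] + 1L
  ry <- (lat$y - 1L) %/% block[2] + 1L
  rz <- (lat$z - 1L) %/% block[3] + 1L
  id <- rx + (ry - 1L) * rpa + (rz - 1L) * rpa * rpa
  nreg <- rpa^3
  cx <- rep_len(seq_len(rpa), nreg)
  cy <- rep(rep(seq_len(rpa), each = rpa), times = rpa)
  cz <- rep(seq_len(rpa), each = rpa * rpa)
  off6 <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  nbreg <- matrix(NA_integer_, nreg, 6)
  for (k in 1:6) {
    x2 <- cx + off6[k, 1]; y2 <- cy + off6[k, 2]; z2 <- cz + off6[k, 3]
    ok <- x2 >= 1L & x2 <= rpa & y2 >= 1L & y2 <= rpa & z2 >= 1L & z2 <= rpa
    idr <- x2 + (y2 - 1L) * rpa + (z2 - 1L) * rpa * rpa
    idr[!ok] <- NA_integer_
    nbreg[, k] <- idr
  }
  boundary <- cx == 1L | cx == rpa | cy == 1L | cy == rpa | cz == 1L | cz == rpa
  list(rpa = rpa, id = id, nreg = nreg, vol = prod(block), block = block,
       nbreg = nbreg, boundary = boundary)
}

# Discrete Laplacian on the region graph (reflecting boundaries).
#' @keywords internal
region_laplacian <- function(v, nbreg) {
  out <- numeric(length(v))
  for (k in seq_len(ncol(nbreg))) {
    j <- nbreg[, k]
    ok <- !is.na(j)
    out[ok] <- out[ok] + v[j[ok]] - v[ok]
  }
  out
}
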
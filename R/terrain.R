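#' Regular-grid slope elevation model
#'
#' A `slope_mesh` is a regular elevation grid in the site frame: node (i, j)
#' sits at `(x0 + (i-1)*dx, y0 + (j-1)*dy)` with elevation `z[i, j]` (metres).
#' Between nodes the surface is the bilinear interpolant, which is continuous
#' across cell boundaries.
#'
#' @param x0,y0 grid origin (metres).
#' @param dx,dy grid spacing (metres), positive.
#' @param z elevation matrix (metres); rows index x, columns index y.
#' @return An object of class `slope_mesh`.
#' @export
slope_mesh <- function(x0, y0, dx, dy, z) {
  z <- as.matrix(z)
  if (dx <= 0 || dy <= 0) stop("grid spacing must be positive")
  if (any(!is.finite(z))) stop("elevations must be finite")
  if (nrow(z) < 2L || ncol(z) < 2L) stop("mesh needs at least 2x2 nodes")
  structure(list(x0 = x0, y0 = y0, dx = dx, dy = dy, z = z),
            class = "slope_mesh")
}

#' @export
print.slope_mesh <- function(x, ...) {
  cat(sprintf("<slope_mesh> %d x %d nodes, spacing %.2f x %.2f m, z in [%.2f, %.2f] m\n",
              nrow(x$z), ncol(x$z), x$dx, x$dy, min(x$z), max(x$z)))
  invisible(x)
}

.mesh_xmax <- function(mesh) mesh$x0 + (nrow(mesh$z) - 1L) * mesh$dx
.mesh_ymax <- function(mesh) mesh$y0 + (ncol(mesh$z) - 1L) * mesh$dy

.mesh_check_bounds <- function(mesh, x, y) {
  eps <- 1e-9
  if (any(x < mesh$x0 - eps | x > .mesh_xmax(mesh) + eps |
          y < mesh$y0 - eps | y > .mesh_ymax(mesh) + eps))
    stop("query point outside mesh bounds")
}

# cell index and local coordinates, vectorized; clamps to the last cell so
# queries exactly on the upper edge stay valid
.mesh_cell <- function(mesh, x, y) {
  fx <- (x - mesh$x0) / mesh$dx
  fy <- (y - mesh$y0) / mesh$dy
  i <- pmin(pmax(floor(fx), 0), nrow(mesh$z) - 2L)
  j <- pmin(pmax(floor(fy), 0), ncol(mesh$z) - 2L)
  list(i = i, j = j, u = fx - i, v = fy - j)
}

#' Bilinear elevation query
#'
#' @param mesh a `slope_mesh`.
#' @param x,y query coordinates (metres), vectorized; must lie inside the grid.
#' @return elevation(s) in metres.
#' @export
elevation <- function(mesh, x, y) {
  .mesh_check_bounds(mesh, x, y)
  c_ <- .mesh_cell(mesh, x, y)
  z00 <- mesh$z[cbind(c_$i + 1L, c_$j + 1L)]
  z10 <- mesh$z[cbind(c_$i + 2L, c_$j + 1L)]
  z01 <- mesh$z[cbind(c_$i + 1L, c_$j + 2L)]
  z11 <- mesh$z[cbind(c_$i + 2L, c_$j + 2L)]
  (1 - c_$u) * (1 - c_$v) * z00 + c_$u * (1 - c_$v) * z10 +
    (1 - c_$u) * c_$v * z01 + c_$u * c_$v * z11
}

# analytic gradient of the bilinear patch, vectorized
.elevation_gradient <- function(mesh, x, y) {
  .mesh_check_bounds(mesh, x, y)
  c_ <- .mesh_cell(mesh, x, y)
  z00 <- mesh$z[cbind(c_$i + 1L, c_$j + 1L)]
  z10 <- mesh$z[cbind(c_$i + 2L, c_$j + 1L)]
  z01 <- mesh$z[cbind(c_$i + 1L, c_$j + 2L)]
  z11 <- mesh$z[cbind(c_$i + 2L, c_$j + 2L)]
  dzdx <- ((1 - c_$v) * (z10 - z00) + c_$v * (z11 - z01)) / mesh$dx
  dzdy <- ((1 - c_$u) * (z01 - z00) + c_$u * (z11 - z10)) / mesh$dy
  cbind(dzdx = dzdx, dzdy = dzdy)
}

#' Local tangent-plane frame of the slope surface
#'
#' Returns the unit surface normal together with an in-plane basis: `ex` is
#' the tangent-plane projection of the site +X axis (the fall-line proxy) and
#' `ey = normal x ex`, so (ex, ey, normal) is right-handed.
#'
#' @param mesh a `slope_mesh`.
#' @param x,y query point (scalar), inside the grid.
#' @return list with unit 3-vectors `normal`, `ex`, `ey`.
#' @export
surface_frame <- function(mesh, x, y) {
  g <- .elevation_gradient(mesh, x, y)
  n <- unname(c(-g[1, 1], -g[1, 2], 1))
  n <- n / sqrt(sum(n^2))
  ex <- c(1, 0, 0) - sum(c(1, 0, 0) * n) * n
  nex <- sqrt(sum(ex^2))
  if (nex < 1e-12) stop("degenerate (vertical) surface: fall line undefined")
  ex <- ex / nex
  ey <- c(n[2] * ex[3] - n[3] * ex[2],
          n[3] * ex[1] - n[1] * ex[3],
          n[1] * ex[2] - n[2] * ex[1])
  list(normal = n, ex = ex, ey = ey)
}

#' Ray-mesh intersection
#'
#' Finds the first crossing of a downward ray with the bilinear surface by
#' marching along the ray (0.1 m default step) until the height above the
#' surface changes sign, then bisecting to |dz| < 1e-6 m. Vectorized over
#' rays: `origin` may be an n-by-3 matrix and `dir` the matching matrix of
#' unit direction vectors.
#'
#' @param mesh a `slope_mesh`.
#' @param origin 3-vector or n-by-3 matrix of ray origins (above the surface).
#' @param dir 3-vector or n-by-3 matrix of unit directions with negative Z.
#' @param step marching step along the ray (metres).
#' @param tol vertical tolerance at the intersection (metres).
#' @return list with `point` (n-by-3 matrix) and `t` (ray parameter, metres;
#'   also the distance for unit `dir`).
#' @export
ray_intersect <- function(mesh, origin, dir, step = 0.1, tol = 1e-6) {
  if (is.null(dim(origin))) origin <- matrix(origin, nrow = 1)
  if (is.null(dim(dir))) dir <- matrix(dir, nrow = 1)
  n <- nrow(origin)
  if (nrow(dir) != n) stop("origin/dir row mismatch")
  if (any(dir[, 3] >= 0)) stop("ray direction must point downward (negative Z)")
  h0 <- origin[, 3] - elevation(mesh, origin[, 1], origin[, 2])
  if (any(h0 <= 0)) stop("ray origin must lie above the surface")

  # height above surface; NA once a ray has left the grid footprint
  height <- function(tt) {
    px <- origin[, 1] + tt * dir[, 1]
    py <- origin[, 2] + tt * dir[, 2]
    pz <- origin[, 3] + tt * dir[, 3]
    inb <- px >= mesh$x0 & px <= .mesh_xmax(mesh) &
           py >= mesh$y0 & py <= .mesh_ymax(mesh)
    h <- rep(NA_real_, length(px))
    if (any(inb)) h[inb] <- pz[inb] - elevation(mesh, px[inb], py[inb])
    h
  }

  # march until every ray has bracketed its first sign change
  lo <- rep(0, n); hi <- rep(NA_real_, n)
  tcur <- rep(0, n)
  tmax <- sqrt((.mesh_xmax(mesh) - mesh$x0)^2 + (.mesh_ymax(mesh) - mesh$y0)^2 +
                 (max(origin[, 3]) - min(mesh$z))^2) + 10
  active <- rep(TRUE, n)
  while (any(active)) {
    tnext <- tcur + step
    if (min(tnext[active]) > tmax) stop("no intersection inside grid")
    hn <- height(tnext)
    if (any(active & is.na(hn))) stop("ray leaves the grid before intersecting")
    newly <- active & hn <= 0
    hi[newly] <- tnext[newly]
    lo[active & !newly] <- tnext[active & !newly]
    active <- active & !newly
    tcur <- tnext
  }

  # bisection on the bracketed interval
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    hm <- height(mid)
    neg <- hm <= 0
    hi[neg] <- mid[neg]
    lo[!neg] <- mid[!neg]
    if (max(abs(hm)) < tol) break
  }
  tt <- (lo + hi) / 2
  pt <- origin + tt * dir
  pt[, 3] <- elevation(mesh, pt[, 1], pt[, 2]) # snap exactly onto the surface
  list(point = pt, t = tt)
}

#' Read / write slope-mesh grid files
#'
#' Plain-text grid dialect: one header line `x0 y0 dx dy nx ny` followed by
#' `nx` lines of `ny` whitespace-separated elevations (row i = constant x).
#'
#' @param path file path.
#' @return `read_mesh()` returns a `slope_mesh`.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 6L || any(is.na(hdr))) stop("malformed mesh header")
  nx <- as.integer(hdr[5]); ny <- as.integer(hdr[6])
  vals <- as.numeric(unlist(strsplit(trimws(lines[-1]), "\\s+")))
  vals <- vals[!is.na(vals)]
  if (length(vals) != nx * ny) stop("mesh value count mismatch")
  slope_mesh(hdr[1], hdr[2], hdr[3], hdr[4],
             matrix(vals, nrow = nx, ncol = ny, byrow = TRUE))
}

#' @rdname read_mesh
#' @param mesh a `slope_mesh`.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "slope_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%.9f %.9f %.9f %.9f %d %d", mesh$x0, mesh$y0,
                     mesh$dx, mesh$dy, nrow(mesh$z), ncol(mesh$z)), con)
  for (i in seq_len(nrow(mesh$z)))
    writeLines(paste(sprintf("%.9f", mesh$z[i, ]), collapse = " "), con)
  invisible(path)
}
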
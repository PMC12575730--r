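#' Construct a density map
#'
#' A `density_map` is a 3D voxel grid with a Cartesian origin: `origin` is
#' the position (Angstrom) of the centre of voxel index (1,1,1), and voxel
#' `(i,j,k)` is centred at `origin + (i-1, j-1, k-1) * voxel_size`. Values
#' are stored float64 internally and written as float32 MRC mode 2.
#'
#' @param grid 3D numeric array (x, y, z order).
#' @param voxel_size length-3 numeric, Angstrom per voxel (or a scalar).
#' @param origin length-3 numeric, Angstrom.
#' @param resolution_hint optional nominal resolution, Angstrom.
#' @return object of class `density_map`.
#' @export
density_map <- function(grid, voxel_size, origin = c(0, 0, 0),
                        resolution_hint = NULL) {
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  stopifnot(length(dim(grid)) == 3, length(voxel_size) == 3,
            length(origin) == 3)
  if (any(voxel_size <= 0)) stop("voxel_size components must be positive")
  if (any(dim(grid) < 2)) stop("grid must have >= 2 voxels per axis")
  if (!all(is.finite(grid))) stop("non-finite density values")
  structure(list(grid = grid, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin),
                 resolution_hint = resolution_hint),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %s voxels @ %.3g,%.3g,%.3g A, origin %.4g,%.4g,%.4g\n",
              paste(dim(x$grid), collapse = "x"),
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Read an MRC/CCP4 density map
#'
#' Supports orthogonal-cell MRC2014 files (modes 0, 1, 2). The axis order
#' is normalised to (x, y, z) using the mapc/mapr/maps header words, and
#' the origin is reconstructed from the ORIGIN record when set, otherwise
#' from nstart and the voxel size.
#'
#' @param path MRC/CCP4 file path.
#' @return a `density_map`.
#' @export
read_map <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  if (length(hdr) < 10) stop("parse error: truncated MRC header in ", path)
  nc <- hdr[1]; nr <- hdr[2]; ns <- hdr[3]; mode <- hdr[4]
  nstart <- hdr[5:7]
  m <- hdr[8:10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  cellb <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  axes <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  if (!(mode %in% c(0, 1, 2)))
    stop("parse error: unsupported or corrupt MRC mode ", mode)
  if (any(abs(cellb - 90) > 1e-3))
    stop("unsupported geometry: non-orthogonal cell (angles ",
         paste(round(cellb, 2), collapse = ", "), ")")
  if (!setequal(axes, 1:3))
    stop("parse error: invalid axis correspondence ",
         paste(axes, collapse = ","))
  seek(con, 196)
  orig <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  seek(con, 1024)
  nvox <- as.double(nc) * nr * ns
  vals <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = nvox, size = 1, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = nvox, size = 2, endian = "little"),
    "2" = readBin(con, "numeric", n = nvox, size = 4, endian = "little"))
  if (length(vals) < nvox)
    stop("parse error: truncated MRC data section in ", path)
  arr <- array(as.numeric(vals), dim = c(nc, nr, ns))
  # permute file (column, row, section) order to Cartesian (x, y, z)
  perm <- match(1:3, axes)
  arr <- aperm(arr, perm)
  m_xyz <- m[perm]
  nstart_xyz <- nstart[perm]
  voxel <- ifelse(m_xyz > 0, cella[1:3] / m_xyz, 1)
  origin <- if (any(abs(orig) > 1e-6)) orig else nstart_xyz * voxel
  density_map(arr, voxel, origin)
}

#' Write a density map as MRC2014 mode 2
#' @param map a `density_map`.
#' @param path output path.
#' @export
write_map <- function(map, path) {
  d <- dim(map$grid)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4,
                             endian = "little")
  wi(d)                       # nx ny nz
  wi(2)                       # mode 2: float32
  wi(c(0, 0, 0))              # nstart
  wi(d)                       # mx my mz
  wf(d * map$voxel_size)      # cella
  wf(c(90, 90, 90))           # cellb
  wi(1:3)                     # mapc mapr maps
  g <- map$grid
  wf(c(min(g), max(g), mean(g)))
  wi(c(1, 0))                 # ispg, nsymbt
  wi(rep(0, 25))              # extra (words 25-49)
  wf(map$origin)              # origin x y z
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # machst little-endian
  wf(stats::sd(as.numeric(g)))
  wi(0)                       # nlabl
  writeBin(raw(800), con)     # labels
  wf(as.numeric(g))
  invisible(path)
}

#' Gaussian spreading configuration
#'
#' Controls how atoms are spread onto the voxel grid when simulating a map
#' from a model: each heavy atom contributes
#' `amplitude * exp(-|r - x|^2 / (2 sigma^2))`, truncated at `cutoff`.
#'
#' @param sigma Gaussian width per atom, Angstrom.
#' @param amplitude_mode `"uniform"` (weight 1 per heavy atom) or
#'   `"atomic_number"`.
#' @param cutoff truncation radius, Angstrom; must be >= 3 sigma
#'   (default 4 sigma, under 0.04 percent truncated mass).
#' @return object of class `spread_config`.
#' @export
spread_config <- function(sigma = 1.5,
                          amplitude_mode = c("uniform", "atomic_number"),
                          cutoff = 4 * sigma) {
  amplitude_mode <- match.arg(amplitude_mode)
  stopifnot(sigma > 0)
  if (cutoff < 3 * sigma) stop("cutoff must be >= 3 * sigma")
  structure(list(sigma = sigma, amplitude_mode = amplitude_mode,
                 cutoff = cutoff), class = "spread_config")
}

#' Spreading width from a nominal resolution
#'
#' Heuristic `sigma = 0.425 * resolution`, i.e. the Gaussian whose FWHM
#' approximately equals the map resolution.
#' @param resolution nominal resolution, Angstrom.
#' @return sigma in Angstrom.
#' @export
sigma_from_resolution <- function(resolution) 0.425 * resolution

ATOMIC_NUMBERS <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16, SE = 34,
                    FE = 26, ZN = 30, MG = 12, CA = 20, MN = 25,
                    "NA" = 11, K = 19, CL = 17)

spread_weights <- function(model, spread) {
  hm <- heavy_mask(model)
  el <- toupper(model$atoms$element[hm])
  w <- if (spread$amplitude_mode == "uniform") rep(1, sum(hm))
  else {
    z <- ATOMIC_NUMBERS[el]
    z[is.na(z)] <- 6
    as.numeric(z)
  }
  list(coords = atom_coords(model)[hm, , drop = FALSE], weights = w)
}

#' Simulate a density map from an atomic model
#'
#' Heavy atoms are spread as truncated Gaussians onto a grid spanning the
#' model bounding box plus `pad` on every side.
#'
#' @param model a `structure_model` with at least one heavy atom.
#' @param voxel_size Angstrom per voxel (scalar or length 3).
#' @param spread a `spread_config`.
#' @param pad margin around the bounding box, Angstrom. A pad smaller than
#'   the truncation cutoff warns (mass is clipped at the box edge).
#' @return a `density_map`.
#' @export
simulate_map <- function(model, voxel_size = 1,
                         spread = spread_config(), pad = spread$cutoff) {
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  sw <- spread_weights(model, spread)
  if (!nrow(sw$coords)) stop("model has no heavy atoms")
  if (pad < spread$cutoff)
    warning("pad < cutoff: Gaussian mass truncated at grid edges")
  lo <- apply(sw$coords, 2, min) - pad
  hi <- apply(sw$coords, 2, max) + pad
  n <- pmax(2L, as.integer(ceiling((hi - lo) / voxel_size)) + 1L)
  grid <- cpp_spread_atoms(sw$coords, sw$weights, n, lo, voxel_size,
                           spread$sigma, spread$cutoff)
  density_map(grid, voxel_size, lo)
}

# spread a model onto the grid of an existing map (same shape/origin),
# returning the raw array; used by model-map cross-correlation
simulate_on_grid <- function(model, target, spread) {
  sw <- spread_weights(model, spread)
  cpp_spread_atoms(sw$coords, sw$weights, dim(target$grid), target$origin,
                   target$voxel_size, spread$sigma, spread$cutoff)
}

gaussian_kernel_1d <- function(sigma_vox) {
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

shift_axis <- function(arr, axis, by) {
  d <- dim(arr)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  n <- d[axis]
  if (by > 0) {
    idx_dst[[axis]] <- (1 + by):n
    idx_src[[axis]] <- 1:(n - by)
  } else if (by < 0) {
    idx_dst[[axis]] <- 1:(n + by)
    idx_src[[axis]] <- (1 - by):n
  }
  out <- array(0, d)
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Blur a density map with an isotropic Gaussian
#'
#' Convolution with a Gaussian of standard deviation `sigma` (Angstrom,
#' converted to voxels per axis), implemented as three separable 1D
#' convolutions with zero padding. The grid and origin are unchanged.
#'
#' @param map a `density_map`.
#' @param sigma blur standard deviation, Angstrom; 0 returns the input.
#' @return a `density_map`.
#' @export
gaussian_blur <- function(map, sigma) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(map)
  g <- map$grid
  for (axis in 1:3) {
    k <- gaussian_kernel_1d(sigma / map$voxel_size[axis])
    r <- (length(k) - 1L) %/% 2L
    if (dim(g)[axis] <= 1) next
    acc <- array(0, dim(g))
    for (o in -r:r) acc <- acc + k[o + r + 1] * shift_axis(g, axis, o)
    g <- acc
  }
  density_map(g, map$voxel_size, map$origin, map$resolution_hint)
}

#' Sample map value and gradient at Cartesian points
#'
#' Trilinear interpolation for the value; the gradient is the analytic
#' derivative of the trilinear interpolant, per Angstrom. Points must lie
#' inside the grid (callers pad first via [pad_map()] if needed).
#'
#' @param map a `density_map`.
#' @param points numeric 3-vector or n x 3 matrix, Angstrom.
#' @return list with `value` (length n) and `gradient` (n x 3).
#' @export
value_and_gradient <- function(map, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  res <- tryCatch(
    cpp_trilinear(map$grid, dim(map$grid), map$origin, map$voxel_size,
                  points),
    error = function(e) stop("boundary error: ", conditionMessage(e)))
  list(value = res[, 1], gradient = res[, 2:4, drop = FALSE])
}

#' Zero-pad a map by whole voxels on every side
#' @param map a `density_map`.
#' @param pad margin in Angstrom (rounded up to whole voxels per axis).
#' @return a `density_map` with enlarged grid and shifted origin.
#' @export
pad_map <- function(map, pad) {
  nv <- as.integer(ceiling(pad / map$voxel_size))
  d <- dim(map$grid)
  g <- array(0, d + 2L * nv)
  g[nv[1] + seq_len(d[1]), nv[2] + seq_len(d[2]), nv[3] + seq_len(d[3])] <-
    map$grid
  density_map(g, map$voxel_size, map$origin - nv * map$voxel_size,
              map$resolution_hint)
}

# pad just enough that all rows of coords sit >= margin inside the grid
pad_map_to_cover <- function(map, coords, margin = 2) {
  d <- dim(map$grid)
  hi_corner <- map$origin + (d - 1L) * map$voxel_size
  need_lo <- max(0, max(map$origin + margin - apply(coords, 2, min)))
  need_hi <- max(0, max(apply(coords, 2, max) - (hi_corner - margin)))
  need <- max(need_lo, need_hi)
  if (need > 0) pad_map(map, need) else map
}
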
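test_that("MRC write/read round trip is exact for float32 values", {
  set.seed(42)
  g <- array(round(rnorm(6^3), 4), dim = c(6, 6, 6))
  g_f32 <- array(readBin(writeBin(as.numeric(g), raw(), size = 4),
                         "numeric", n = length(g), size = 4), dim(g))
  m <- density_map(g_f32, c(1.0, 1.0, 1.3), origin = c(-3, 2, 7.5))
  path <- tempfile(fileext = ".mrc")
  write_map(m, path)
  m2 <- read_map(path)
  expect_identical(dim(m2$grid), dim(m$grid))
  expect_equal(m2$grid, m$grid)          # values already float32-exact
  expect_equal(m2$voxel_size, c(1.0, 1.0, 1.3), tolerance = 1e-6)
  expect_equal(m2$origin, c(-3, 2, 7.5), tolerance = 1e-6)

  z <- density_map(array(0, c(4, 4, 4)), 1)
  pz <- tempfile(fileext = ".mrc")
  write_map(z, pz)
  expect_equal(read_map(pz)$grid, z$grid)
})

test_that("axis-permuted MRC files are normalised to x,y,z order", {
  set.seed(7)
  g <- array(rnorm(3 * 4 * 5), dim = c(3, 4, 5))
  ref <- density_map(g, c(1, 1, 1), origin = c(0, 0, 0))
  # write a permuted twin by hand: file stores (y, z, x) sections
  perm <- c(2, 3, 1)                     # file col/row/sec hold axes y,z,x
  arr_file <- aperm(g, perm)
  path <- tempfile(fileext = ".mrc")
  con <- file(path, "wb")
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(dim(arr_file)); wi(2); wi(c(0, 0, 0)); wi(dim(arr_file))
  wf(dim(arr_file) * 1.0); wf(c(90, 90, 90)); wi(perm)
  wf(c(min(g), max(g), mean(g))); wi(c(1, 0)); wi(rep(0, 25))
  wf(c(0, 0, 0))
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x41, 0, 0)), con)
  wf(sd(g)); wi(0); writeBin(raw(800), con)
  wf(as.numeric(arr_file))
  close(con)
  m <- read_map(path)
  expect_identical(dim(m$grid), dim(ref$grid))
  expect_equal(m$grid, ref$grid, tolerance = 1e-6)
})

test_that("truncated and non-orthogonal MRC files raise parse errors", {
  path <- tempfile(fileext = ".mrc")
  writeBin(as.raw(1:100), path)
  expect_error(read_map(path), "parse error|truncated")
  m <- density_map(array(1:8, c(2, 2, 2)) * 1.0, 1)
  p2 <- tempfile(fileext = ".mrc")
  write_map(m, p2)
  # corrupt the beta cell angle (bytes 56-60 hold cellb[2])
  con <- file(p2, "r+b"); seek(con, 56, rw = "write")
  writeBin(70, con, size = 4, endian = "little"); close(con)
  expect_error(read_map(p2), "non-orthogonal")
})

test_that("simulate_map matches the closed-form Gaussian for one atom", {
  m1 <- two_atom_model(60)              # two atoms, far apart
  single <- structure_model(m1$atoms[1, , drop = FALSE], validate = FALSE)
  sp <- spread_config(sigma = 1.5)
  dm <- simulate_map(single, 1, sp, pad = 8)
  peak_idx <- which(dm$grid == max(dm$grid), arr.ind = TRUE)[1, ]
  peak_pos <- dm$origin + (peak_idx - 1) * dm$voxel_size
  expect_equal(peak_pos, c(0, 0, 0), tolerance = 1e-6, ignore_attr = TRUE)
  # value at distance d is max * exp(-d^2 / (2 sigma^2))
  probe <- dm$grid[peak_idx[1] + 3, peak_idx[2], peak_idx[3]]
  expect_equal(probe / max(dm$grid), exp(-9 / (2 * 1.5^2)),
               tolerance = 1e-6)
})

test_that("well-separated atoms superpose additively", {
  m <- two_atom_model(60)
  sp <- spread_config(sigma = 1.5)
  both <- simulate_map(m, 1, sp)
  a <- structure_model(m$atoms[1, , drop = FALSE], validate = FALSE)
  da <- simulate_map(a, 1, sp, pad = 6)
  expect_equal(sum(both$grid), 2 * sum(da$grid), tolerance = 1e-6)
  expect_equal(max(both$grid), max(da$grid), tolerance = 1e-6)
})

test_that("translating the model by one voxel shifts grid values by one index", {
  m <- make_helix(6)
  sp <- spread_config(sigma = 1.2)
  d1 <- simulate_map(m, 1, sp, pad = 6)
  m2 <- m
  m2$atoms$x <- m$atoms$x + 1
  d2 <- simulate_map(m2, 1, sp, pad = 6)
  expect_equal(d2$origin, d1$origin + c(1, 0, 0), tolerance = 1e-9)
  expect_equal(d2$grid, d1$grid, tolerance = 1e-9)
})

test_that("gaussian_blur: identity at sigma 0, closed-form kernel, mass conservation", {
  g <- array(0, c(15, 15, 15))
  g[8, 8, 8] <- 1
  m <- density_map(g, 1)
  expect_identical(gaussian_blur(m, 0)$grid, g)
  b <- gaussian_blur(m, 1)
  # separable sampled-kernel prediction at an offset voxel
  k1 <- exp(-(-4:4)^2 / 2); k1 <- k1 / sum(k1)
  expect_equal(b$grid[8, 8, 8], k1[5]^3, tolerance = 1e-6)
  expect_equal(b$grid[9, 8, 8], k1[5]^2 * k1[6], tolerance = 1e-6)
  expect_equal(sum(b$grid), 1, tolerance = 1e-3)
  # peak height is monotone non-increasing in sigma
  peaks <- vapply(c(0.5, 1, 1.5, 2), function(s)
    max(gaussian_blur(m, s)$grid), 0)
  expect_true(all(diff(peaks) <= 1e-12))
})

test_that("blurring a simulated map widens it like a wider spread", {
  m <- structure_model(two_atom_model(60)$atoms[1, , drop = FALSE],
                       validate = FALSE)
  s1 <- 1.2; s2 <- 1.0
  a <- gaussian_blur(simulate_map(m, 1, spread_config(s1, cutoff = 8),
                                  pad = 12), s2)
  b <- simulate_map(m, 1, spread_config(sqrt(s1^2 + s2^2), cutoff = 8),
                    pad = 12)
  # normalise amplitudes (blur conserves mass, widening does not)
  av <- a$grid / max(a$grid)
  bv <- b$grid / max(b$grid)
  expect_lt(sqrt(mean((av - bv)^2)) / sqrt(mean(bv^2)), 0.01)
})

test_that("value_and_gradient reproduces nodes, linear ramps, and the 8-corner oracle", {
  set.seed(31)
  g <- array(rnorm(6 * 5 * 7), c(6, 5, 7))
  m <- density_map(g, c(1, 2, 1.5), origin = c(10, -4, 2))
  # grid node
  vg <- value_and_gradient(m, c(10 + 2 * 1, -4 + 3 * 2, 2 + 4 * 1.5))
  expect_equal(vg$value, g[3, 4, 5], tolerance = 1e-12)
  # linear ramp f = x has unit gradient per Angstrom
  ramp <- density_map(array(rep(seq_len(6), 5 * 7), c(6, 5, 7)) * 2.5,
                      c(0.5, 1, 1))
  vr <- value_and_gradient(ramp, c(1.23, 2.1, 3.4))
  expect_equal(unname(vr$gradient[1, ]), c(2.5 / 0.5, 0, 0),
               tolerance = 1e-9)
  # brute-force 8-corner weighted sum at random interior points
  for (i in 1:20) {
    p <- c(runif(1, 10.1, 14.9), runif(1, -3.9, 3.9), runif(1, 2.1, 10.9))
    f <- (p - m$origin) / m$voxel_size
    i0 <- floor(f); t <- f - i0
    val <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- prod(ifelse(c(dx, dy, dz) == 1, t, 1 - t))
      val <- val + w * g[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
    }
    expect_equal(value_and_gradient(m, p)$value, val, tolerance = 1e-9)
  }
  expect_error(value_and_gradient(m, c(200, 0, 0)), "boundary")
})

test_that("pad_map embeds the grid and preserves sampled values", {
  set.seed(3)
  g <- array(rnorm(4^3), c(4, 4, 4))
  m <- density_map(g, 1, origin = c(5, 5, 5))
  p <- pad_map(m, 2)
  expect_identical(dim(p$grid), dim(g) + 4L)
  expect_equal(p$origin, c(3, 3, 3))
  expect_equal(value_and_gradient(p, c(6, 7, 5))$value,
               value_and_gradient(m, c(6, 7, 5))$value, tolerance = 1e-12)
})
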
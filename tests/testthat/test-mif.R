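em0 <- energy_model()

test_that("grids wrap the site bounding box at the requested spacing", {
  one <- charge_structure(c(0, 0, 0), charge = 0)
  g <- make_grid(one, spacing = 1, margin = 4)
  expect_equal(g$shape, c(9L, 9L, 9L))
  expect_equal(g$origin, c(-4, -4, -4))
  g0 <- make_grid(one, spacing = 1, margin = 0)
  expect_equal(g0$shape, c(1L, 1L, 1L))
  two <- charge_structure(rbind(c(0, 0, 0), c(10, 0, 0)), charge = 0)
  expect_equal(make_grid(two)$shape[1], 19L)
  expect_error(make_grid(one, spacing = 0), "positive")
})

test_that("a fully neutral probe produces an identically zero field", {
  s <- charge_structure(rbind(c(0, 0, 0), c(3, 1, -2)), charge = c(1, -1))
  probe <- probe_params("ghost", charge = 0, eps = 0, radius = 1)
  f <- compute_field(s, probe, em0, make_grid(s, spacing = 2))
  expect_true(all(f$values == 0))
})

test_that("the Coulomb term matches the closed form under eps(r) = 4r", {
  s <- charge_structure(c(0, 0, 0), charge = 1, eps = 0)  # no LJ
  n1 <- probe_params("N1+", eps = 0)
  # +1 probe vs +1 atom at r = 4: 332/(4*4*4) = 5.1875, clamped to 5
  raw <- field_at_points(s, n1, em0, rbind(c(4, 0, 0)), clamp = FALSE)
  expect_equal(raw, 332 / (4 * 4 * 4))
  expect_equal(raw, 5.1875)
  clamped <- field_at_points(s, n1, em0, rbind(c(4, 0, 0)))
  expect_equal(clamped, 5)
  # anionic atom attracts the cationic probe
  s_neg <- charge_structure(c(0, 0, 0), charge = -1, eps = 0)
  expect_equal(field_at_points(s_neg, n1, em0, rbind(c(4, 0, 0))), -5.1875)
})

test_that("every node matches the brute-force double-loop oracle", {
  s <- simulate_scaffold("good", seed = 21)
  grid <- make_grid(s, spacing = 1.5, margin = 3)
  for (pn in c("N1+", "DRY", "OH2")) {
    p <- probe_params(pn)
    f <- compute_field(s, p, em0, grid)
    expect_equal(f$values, brute_force_field(s, p, em0, grid),
                 tolerance = 1e-10)
  }
  # with a distance cutoff too
  em_cut <- energy_model(cutoff = 6)
  p <- probe_params("N1+")
  expect_equal(compute_field(s, p, em_cut, grid)$values,
               brute_force_field(s, p, em_cut, grid), tolerance = 1e-10)
})

test_that("flipping atom charges flips the unclamped Coulomb field", {
  s <- charge_structure(rbind(c(0, 0, 0), c(4, 0, 0)), charge = c(-1, -0.5),
                        eps = 0)
  s_flip <- s
  s_flip$atom$charge <- -s$atom$charge
  p <- probe_params("N1+", eps = 0)
  pts <- matrix(rnorm(60, sd = 6), 20, 3)
  e1 <- field_at_points(s, p, em0, pts, clamp = FALSE)
  e2 <- field_at_points(s_flip, p, em0, pts, clamp = FALSE)
  expect_equal(e1, -e2, tolerance = 1e-12)
})

test_that("fields are invariant under joint rigid motion", {
  s <- simulate_scaffold("good", seed = 13)
  p <- probe_params("N1+")
  set.seed(31)
  pts <- matrix(rnorm(45, sd = 5), 15, 3)
  e0 <- field_at_points(s, p, em0, pts)
  rot <- random_rotation(5)
  shift <- c(2, -7, 4)
  s2 <- s
  xyz <- coords(s) %*% t(rot) + matrix(shift, nrow(coords(s)), 3,
                                       byrow = TRUE)
  s2$atom$x <- xyz[, 1]; s2$atom$y <- xyz[, 2]; s2$atom$z <- xyz[, 3]
  pts2 <- pts %*% t(rot) + matrix(shift, nrow(pts), 3, byrow = TRUE)
  expect_equal(field_at_points(s2, p, em0, pts2), e0, tolerance = 1e-8)
})

test_that("halving the spacing reproduces coarse-grid values at shared nodes", {
  s <- simulate_scaffold("poor", seed = 2)
  p <- probe_params("DRY")
  coarse <- compute_field(s, p, em0, make_grid(s, spacing = 2, margin = 2))
  fine_spec <- make_grid(s, spacing = 1, margin = 2)
  fine <- compute_field(s, p, em0, fine_spec)
  nx <- coarse$spec$shape
  shared <- fine$values[seq(1, 2 * nx[1] - 1, 2),
                        seq(1, 2 * nx[2] - 1, 2),
                        seq(1, 2 * nx[3] - 1, 2)]
  expect_equal(shared, coarse$values, tolerance = 1e-12)
})

test_that("clamping only affects the near field of modest charges", {
  s <- simulate_scaffold("good", seed = 17)
  p <- probe_params("N1+")
  grid <- make_grid(s, spacing = 1, margin = 4)
  raw <- field_at_points(s, p, em0, grid_nodes(grid), clamp = FALSE)
  clamped <- as.vector(compute_field(s, p, em0, grid)$values)
  xyz <- coords(s)
  rmax <- 2 * (p$radius + max(s$atom$radius))
  dmin <- apply(grid_nodes(grid), 1, function(pt) {
    min(sqrt(colSums((t(xyz) - pt)^2)))
  })
  far <- dmin > rmax
  expect_equal(clamped[far], raw[far], tolerance = 1e-12)
})

test_that("OpenDX export round trips and uses z-fastest ordering", {
  spec <- structure(list(origin = c(0, 0, 0), spacing = 1,
                         shape = c(2L, 2L, 2L)), class = "grid_spec")
  zero <- structure(list(spec = spec, probe = "OH2",
                         values = array(0, c(2, 2, 2))),
                    class = "grid_field")
  f <- tempfile(fileext = ".dx")
  write_dx(zero, f)
  body <- readLines(f)
  start <- grep("data follows", body)
  vals <- as.numeric(unlist(strsplit(trimws(
    body[(start + 1):(start + 3)]), "\\s+")))
  expect_equal(vals, rep(0, 8))

  # hand-written file: value at (x=2, y=1, z=1) is the 5th in z-fastest order
  hand <- structure(list(spec = spec, probe = "t",
                         values = array(1:8, c(2, 2, 2))),
                    class = "grid_field")
  write_dx(hand, f)
  body <- readLines(f)
  start <- grep("data follows", body)
  vals <- as.numeric(unlist(strsplit(trimws(
    body[(start + 1):(start + 3)]), "\\s+")))
  # x-fastest storage 1..8 -> z-fastest stream: (1,1,1),(1,1,2),(1,2,1),...
  expect_equal(vals, c(1, 5, 3, 7, 2, 6, 4, 8))

  s <- simulate_scaffold("good", seed = 3)
  fld <- compute_field(s, probe_params("N1+"), em0,
                       make_grid(s, spacing = 2, margin = 2))
  write_dx(fld, f)
  back <- read_dx(f, probe = "N1+")
  expect_equal(back$spec$origin, fld$spec$origin, tolerance = 1e-6)
  expect_equal(back$spec$shape, fld$spec$shape)
  expect_equal(back$values, fld$values, tolerance = 1e-6)
})
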
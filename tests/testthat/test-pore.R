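sch <- generator_scheme()

z_axis <- structure(list(origin = c(0, 0, 0), direction = c(0, 0, 1)),
                    class = "pore_axis")

# hand-built cylinder of carbon pseudo-atoms: n_per per ring at radius R
cylinder_model <- function(ring_radii, ring_z, n_per = 10) {
  rows <- purrr::map2_dfr(ring_radii, ring_z, function(R, z0) {
    th <- 2 * pi * (seq_len(n_per) - 1) / n_per
    tibble::tibble(chain = "A", res_seq = seq_len(n_per) + round(z0 * 100),
                   res_name = "GLY", atom_name = "CA", element = "C",
                   x = R * cos(th), y = R * sin(th), z = z0,
                   is_hetero = FALSE)
  })
  rows <- rows |> dplyr::arrange(res_seq)
  pent_structure(rows)
}

# exhaustive in-plane maximin search on a 0.05 A grid — the brute-force
# oracle the probe must agree with
grid_oracle <- function(model, z0, vdw = 1.7, span = 4, step = 0.05) {
  xyz <- pentagate:::model_coords(model)
  g <- seq(-span, span, by = step)
  best <- -Inf
  for (gx in g) for (gy in g) {
    r <- min(sqrt((gx - xyz[, 1])^2 + (gy - xyz[, 2])^2 + (z0 - xyz[, 3])^2)) - vdw
    if (r > best) best <- r
  }
  best
}

test_that("probe radius on an ideal cylinder matches R - r_vdw", {
  m <- cylinder_model(rep(5, 4), c(0, 2, 4, 6), n_per = 10)
  prof <- pore_radius_profile(m, axis = z_axis, z_window = c(0, 6),
                              z_step = 2, cylinder_radius = 20)
  expect_equal(prof$radius, rep(5 - 1.7, 4), tolerance = 1e-3)
  expect_false(any(prof$capped))
  # between rings the nearest atoms sit one z-step off-plane
  mid <- pore_radius_profile(m, axis = z_axis, z_window = c(3, 3),
                             z_step = 1, cylinder_radius = 20)
  expect_equal(mid$radius, sqrt(5^2 + 1^2) - 1.7, tolerance = 1e-3)
})

test_that("a squeezed ring produces the analytic local minimum", {
  m <- cylinder_model(c(5, 5, 3, 5, 5), c(0, 2, 4, 6, 8), n_per = 12)
  prof <- pore_radius_profile(m, axis = z_axis, z_window = c(0, 8),
                              z_step = 0.5, cylinder_radius = 20)
  at4 <- prof$radius[abs(prof$z - 4) < 1e-9]
  expect_equal(at4, 3 - 1.7, tolerance = 1e-3)
  expect_equal(min(prof$radius), at4, tolerance = 1e-9)
})

test_that("the probe agrees with an exhaustive 0.05 A grid search", {
  set.seed(14)
  # an irregular toy pore: jittered rings of varying radius
  rows <- purrr::map_dfr(1:5, function(j) {
    n <- 10
    th <- 2 * pi * (seq_len(n) - 1) / n + runif(1, 0, 0.6)
    R <- runif(n, 3.5, 6.5)
    tibble::tibble(chain = "A", res_seq = j * 100 + seq_len(n),
                   res_name = "GLY", atom_name = "CA", element = "C",
                   x = R * cos(th), y = R * sin(th),
                   z = 2 * j + rnorm(n, sd = 0.3), is_hetero = FALSE)
  })
  m <- pent_structure(rows)
  for (z0 in c(4, 6, 8)) {
    prof <- pore_radius_profile(m, axis = z_axis, z_window = c(z0, z0),
                                z_step = 1, cylinder_radius = 20)
    expect_equal(prof$radius, grid_oracle(m, z0), tolerance = 0.05,
                 info = paste("z =", z0))
  }
})

test_that("inflating every vdW radius shrinks the profile monotonically", {
  m <- cylinder_model(c(5, 4, 5), c(0, 2, 4), n_per = 12)
  vdw1 <- vdw_radii()
  vdw2 <- vdw1 + 0.3
  p1 <- pore_radius_profile(m, axis = z_axis, z_window = c(0, 4),
                            z_step = 0.5, vdw = vdw1, cylinder_radius = 20)
  p2 <- pore_radius_profile(m, axis = z_axis, z_window = c(0, 4),
                            z_step = 0.5, vdw = vdw2, cylinder_radius = 20)
  expect_true(all(p2$radius <= p1$radius + 1e-9))
})

test_that("profiles are invariant under rigid motion of frame plus axis", {
  m <- cylinder_model(c(5, 4, 5), c(0, 2, 4), n_per = 12)
  p1 <- pore_radius_profile(m, axis = z_axis, z_window = c(0, 4),
                            z_step = 1, cylinder_radius = 20)
  set.seed(77)
  rig <- random_rigid()
  m2 <- move_model(m, rig)
  ax2 <- structure(list(origin = as.vector(move_rigid(matrix(c(0, 0, 0), 1), rig)),
                        direction = as.vector(rig$R %*% c(0, 0, 1))),
                   class = "pore_axis")
  p2 <- pore_radius_profile(m2, axis = ax2, z_window = c(0, 4),
                            z_step = 1, cylinder_radius = 20)
  expect_equal(p2$radius, p1$radius, tolerance = 1e-6)
})

test_that("unconfined samples are capped and flagged", {
  m <- cylinder_model(c(5, 5), c(0, 2), n_per = 10)
  expect_warning(
    prof <- pore_radius_profile(m, axis = z_axis, z_window = c(0, 30),
                                z_step = 10, cap_radius = 8,
                                cylinder_radius = 20),
    "capped"
  )
  expect_true(any(prof$capped))
  expect_true(all(prof$radius <= 8))
})

test_that("profile statistics match closed-form SEM cases", {
  p <- tibble::tibble(frame = rep(1:3, each = 2), z = rep(c(0, 1), 3),
                      radius = rep(c(2, 3), 3))
  out <- profile_stats(p)
  expect_equal(out$radius_sem, c(0, 0))

  p2 <- tibble::tibble(frame = rep(1:2, each = 1), z = 0, radius = c(2, 4))
  out2 <- profile_stats(p2)
  expect_equal(out2$radius_mean, 3)
  expect_equal(out2$radius_sem, 1)  # SD sqrt(2), /sqrt(2)

  set.seed(31)
  sigma <- 0.5
  p3 <- tibble::tibble(frame = rep(1:100, each = 1), z = 0,
                       radius = 3 + rnorm(100, sd = sigma))
  out3 <- profile_stats(p3)
  expect_equal(out3$radius_sem, sigma / 10, tolerance = 0.2)
})

test_that("prime annotations land on the constructed ring positions", {
  m <- build_pentamer(pentamer_spec())
  prof <- pore_radius_profile(m, scheme = sch, z_window = c(-9, 1),
                              z_step = 0.5)
  prof <- annotate_primes(prof, m, sch)
  primes <- attr(prof, "primes")
  expect_equal(nrow(primes), 3)
  # the generator builds the 2' ring at probe radius 1.5 A
  expect_equal(primes$radius[primes$label == "2'"], 1.5, tolerance = 0.02)
  expect_equal(primes$radius[primes$label == "9'"], 3.0, tolerance = 0.02)

  expect_warning(annotate_primes(prof, m, domain_scheme()), "prime_map")
})

test_that("trajectory profiles average ring radii across frames", {
  tr <- build_trajectory(pentamer_spec(seed = 9), 3)
  al <- align_trajectory(tr, scheme = sch)
  long <- traj_pore_profiles(al, frames = 1:3, scheme = sch,
                             z_window = c(-8, -4), z_step = 2)
  expect_equal(nrow(long), 9)
  st <- profile_stats(long)
  expect_equal(st$n, rep(3, 3))
  expect_equal(st$radius_sem, rep(0, 3), tolerance = 1e-9)  # static frames
  # the inner (2') ring lies at axis coordinate -8 with probe radius 1.5
  expect_equal(st$radius_mean[st$z == -8], 1.5, tolerance = 1e-3)
})
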
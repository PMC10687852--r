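test_that("switched pair potential honours its anchor points", {
  p <- lj_params()
  rmin <- 2^(1 / 6) * p$sigma
  expect_equal(pair_potential(rmin, p), -p$epsilon, tolerance = 1e-12)
  expect_equal(pair_potential(p$sigma, p), 0, tolerance = 1e-12)
  expect_equal(pair_potential(1.25, p), 0)
  expect_equal(pair_potential(5, p), 0)
  expect_error(pair_potential(-0.1, p), "positive")
  # continuity across the switch window boundaries
  eps <- 1e-7
  expect_equal(pair_potential(p$switch_start - eps, p),
               pair_potential(p$switch_start + eps, p), tolerance = 1e-5)
  expect_equal(pair_potential(p$cutoff - eps, p), 0, tolerance = 1e-5)
  # once-differentiable: symmetric difference quotients converge
  num_d <- function(r, h) (pair_potential(r + h, p) -
                           pair_potential(r - h, p)) / (2 * h)
  expect_equal(num_d(1.1, 1e-5), num_d(1.1, 1e-6), tolerance = 1e-3)
  expect_error(lj_params(sigma = 1.1, switch_start = 1.0), "sigma")
})

test_that("total energies sum hand-computed minimum-image pair terms", {
  sv <- lj_params(sigma = 0.34, epsilon = 1, switch_start = 0.6, cutoff = 0.8)
  spec <- system_spec(n_solvent = 3, box_length = 2, solvent_params = sv,
                      solute_params = NULL)
  rmin <- 2^(1 / 6) * sv$sigma
  pos <- rbind(c(0.5, 0.5, 0.5), c(0.5 + rmin, 0.5, 0.5), c(1.9, 0.5, 0.5))
  # manual plain-LJ oracle (all three distances below the switch onset,
  # except pair 2-3 which sits inside the switch window)
  lj <- function(r) 4 * (0.34 / r)^6 * ((0.34 / r)^6 - 1)
  sw <- function(r) {
    x <- (r - 0.6) / 0.2
    if (r <= 0.6) 1 else if (r >= 0.8) 0 else 1 - x^3 * (10 - 15 * x + 6 * x^2)
  }
  d12 <- rmin
  d13 <- 0.5 + 0.1  # via the periodic boundary: 0.5 - (1.9 - 2)
  d23 <- 1.9 - 0.5 - rmin
  manual <- sum(vapply(c(d12, d13, d23), function(r)
    if (r >= 0.8) 0 else lj(r) * sw(r), 0))
  e <- total_energies(pos, spec)
  expect_equal(e$U_vv, manual, tolerance = 1e-10)
  expect_equal(e$U_uv, 0)
  # two particles at the LJ minimum: exactly -epsilon
  spec2 <- system_spec(n_solvent = 2, box_length = 2, solvent_params = sv,
                       solute_params = NULL)
  e2 <- total_energies(rbind(c(0.5, 0.5, 0.5), c(0.5 + rmin, 0.5, 0.5)), spec2)
  expect_equal(e2$U_vv, -sv$epsilon, tolerance = 1e-12)
})

test_that("a decoupled solute contributes no energy at any configuration", {
  spec <- reduced_argon_spec(48, lambda = 0)
  set.seed(2)
  pos <- matrix(stats::runif(48 * 3, 0, spec$box_length), 48, 3)
  e <- total_energies(pos, spec)
  expect_equal(e$U_uv, 0)
  run <- mc_run(spec, sim_config(n_steps = 5000, equilibration_steps = 1000,
                                 output_stride = 500, seed = 3))
  expect_true(all(run$energies$U_uv == 0))
})

test_that("Monte Carlo runs are seed-reproducible with exact bookkeeping", {
  spec <- reduced_argon_spec(48)
  cfg <- sim_config(n_steps = 30000, equilibration_steps = 5000,
                    output_stride = 1000, seed = 11)
  a <- mc_run(spec, cfg)
  b <- mc_run(spec, cfg)
  expect_identical(a$energies, b$energies)
  expect_identical(a$trajectory$coords, b$trajectory$coords)
  expect_lt(a$bookkeeping_error, 1e-8)
  expect_equal(nrow(a$energies), 30)
  expect_equal(n_frames(a$trajectory), 30)
  expect_true(a$acceptance > 0.2 && a$acceptance < 0.8)
  # solute is immobilized: solvent count unchanged, coordinates in box
  expect_true(all(a$trajectory$coords >= 0 &
                  a$trajectory$coords <= spec$box_length))
})

test_that("an ideal gas samples the box uniformly", {
  sv <- lj_params(sigma = 0.1, epsilon = 0, switch_start = 0.3, cutoff = 0.4)
  spec <- system_spec(n_solvent = 27, box_length = 1.5, solvent_params = sv,
                      solute_params = NULL)
  run <- mc_run(spec, sim_config(n_steps = 27 * 2000,
                                 equilibration_steps = 27 * 200,
                                 output_stride = 27 * 20, seed = 21))
  x <- as.vector(run$trajectory$coords[, , 1])
  ks <- stats::ks.test(x, "punif", 0, 1.5)
  expect_gt(ks$p.value, 0.01)
})

test_that("two cold particles concentrate at the potential minimum", {
  sv <- lj_params(sigma = 0.34, epsilon = 1, switch_start = 0.6, cutoff = 0.8)
  spec <- system_spec(n_solvent = 2, box_length = 1.7, temperature = 15,
                      solvent_params = sv, solute_params = NULL)
  run <- mc_run(spec, sim_config(n_steps = 2e5, equilibration_steps = 2e4,
                                 output_stride = 100, seed = 4,
                                 max_displacement = 0.02))
  d <- vapply(seq_len(n_frames(run$trajectory)), function(f) {
    p <- get_frame(run$trajectory, f)
    dx <- abs(p[1, ] - p[2, ])
    sqrt(sum(pmin(dx, 1.7 - dx)^2))
  }, 0)
  # median: robust against the rare thermally activated dissociations
  expect_lt(abs(stats::median(d) - 2^(1 / 6) * 0.34), 0.02)
})

test_that("the sampled pair-distance distribution obeys detailed balance", {
  # 2 particles: P(r) proportional to r^2 exp(-beta U(r)) (up to box effects
  # kept small by comparing only within r < box/4)
  sv <- lj_params(sigma = 0.34, epsilon = 0.9, switch_start = 0.6,
                  cutoff = 0.8)
  spec <- system_spec(n_solvent = 2, box_length = 2.0, temperature = 120,
                      solvent_params = sv, solute_params = NULL)
  run <- mc_run(spec, sim_config(n_steps = 6e5, equilibration_steps = 4e4,
                                 output_stride = 60, seed = 8))
  d <- vapply(seq_len(n_frames(run$trajectory)), function(f) {
    p <- get_frame(run$trajectory, f)
    dx <- abs(p[1, ] - p[2, ])
    sqrt(sum(pmin(dx, 2.0 - dx)^2))
  }, 0)
  beta <- 1 / (0.008314462618 * 120)
  breaks <- seq(0.3, 0.5, by = 0.025)
  obs <- hist(d[d >= 0.3 & d < 0.5], breaks = breaks, plot = FALSE)$counts
  mids <- head(breaks, -1) + 0.0125
  expectd <- mids^2 * exp(-beta * pair_potential(mids, sv))
  expectd <- expectd / sum(expectd) * sum(obs)
  expect_gt(stats::cor(obs, expectd), 0.98)
  expect_lt(max(abs(obs - expectd) / sum(obs)), 0.05)
})

test_that("independent seeds agree on the mean solvent energy", {
  spec <- reduced_argon_spec(64)
  runs <- lapply(c(101, 202), function(s)
    mc_run(spec, sim_config(n_steps = 64 * 1500,
                            equilibration_steps = 64 * 300,
                            output_stride = 64 * 10, seed = s),
           store_frames = FALSE))
  stats_of <- function(r) c(mean(r$energies$U_vv),
                            stats::sd(r$energies$U_vv) /
                              sqrt(nrow(r$energies)))
  s1 <- stats_of(runs[[1]])
  s2 <- stats_of(runs[[2]])
  expect_lt(abs(s1[1] - s2[1]), 3 * sqrt(s1[2]^2 + s2[2]^2))
})

test_that("the soft-core coupling derivative matches finite differences", {
  spec <- reduced_argon_spec(48)
  set.seed(14)
  pos <- matrix(stats::runif(48 * 3, 0, spec$box_length), 48, 3)
  for (lam in c(0.05, 0.3, 0.7)) {
    sp <- spec; sp$lambda <- lam + 1e-6
    sm <- spec; sm$lambda <- lam - 1e-6
    s0 <- spec; s0$lambda <- lam
    fd <- (total_energies(pos, sp)$U_uv - total_energies(pos, sm)$U_uv) / 2e-6
    expect_equal(total_energies(pos, s0)$dU_dlambda, fd, tolerance = 1e-5)
  }
})

test_that("TI windows behave at the endpoints and match FEP", {
  sv <- lj_params(sigma = 0.3405, epsilon = 0.996, switch_start = 0.45,
                  cutoff = 0.58)
  su <- lj_params(sigma = 0.3405, epsilon = 1.5, switch_start = 0.45,
                  cutoff = 0.58)
  spec <- system_spec(n_solvent = 32, box_length = 1.221,
                      solvent_params = sv, solute_params = su)
  cfg <- sim_config(n_steps = 32 * 2000, equilibration_steps = 32 * 500,
                    output_stride = 32 * 10, seed = 17)
  grid <- lambda_grid(21)
  curve <- ti_particles(spec, grid, cfg)
  expect_equal(nrow(curve), 21)
  expect_equal(curve$mean_uv[1], 0)   # lambda = 0 window has no coupling
  dec <- canonical_decompose(curve, beta = 1 / (0.008314462618 * 120))
  expect_identical(dec$dU_vv - dec$TdS_vv, 0)
  fep <- fep_free_energy(spec, grid, cfg)
  expect_lt(abs(fep$dF - dec$dF),
            3 * sqrt(dec$stderr[["dF"]]^2 + fep$stderr^2))
})
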
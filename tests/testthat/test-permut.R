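test_that("assignment cost is the minimum-image squared displacement", {
  ref <- rbind(c(0.1, 0.1, 0.1), c(0.9, 0.9, 0.9), c(0.5, 0.5, 0.5))
  expect_equal(diag(assignment_cost(ref, ref, box = 1)), rep(0, 3))
  swapped <- ref[c(2, 1, 3), ]
  cs <- assignment_cost(swapped, ref, box = 1)
  expect_equal(cs[1, 2], 0)
  expect_equal(cs[2, 1], 0)
  # hand computation, including wrap-around: 0.1 vs 0.9 is 0.2 apart
  expect_equal(cs[1, 1], 3 * 0.2^2, tolerance = 1e-12)
  expect_error(assignment_cost(ref, ref, box = 1,
                               species = c("A", "A", "B"),
                               ref_species = c("A", "B", "B")),
               "species")
})

test_that("optimal assignment matches exhaustive search for n <= 6", {
  set.seed(123)
  for (rep in 1:100) {
    n <- sample(2:6, 1)
    cost <- matrix(stats::runif(n * n), n, n)
    a <- solve_assignment(cost)
    brute <- brute_assignment(cost)
    expect_equal(sum(cost[cbind(seq_len(n), a)]), brute$cost,
                 tolerance = 1e-12)
  }
})

test_that("permutation reduction undoes label swaps and conserves coordinates", {
  set.seed(9)
  base <- matrix(stats::runif(5 * 3, 0, 2), 5, 3)
  frames <- list(base, base[c(2, 1, 3, 4, 5), ], base[c(1, 2, 5, 4, 3), ])
  traj <- toy_trajectory(frames, box = 2)
  red <- permutation_reduce(traj, base)
  for (f in 1:3) expect_equal(get_frame(red, f), base, tolerance = 1e-12)
  # multiset of coordinates per frame unchanged under reduction
  jiggled <- lapply(1:4, function(i) (base + stats::rnorm(15, 0, 0.05)) %% 2)
  traj2 <- toy_trajectory(jiggled, box = 2)
  red2 <- permutation_reduce(traj2, base)
  for (f in 1:4) {
    a <- get_frame(traj2, f)
    b <- get_frame(red2, f)
    expect_equal(a[do.call(order, as.data.frame(a)), ],
                 b[do.call(order, as.data.frame(b)), ])
  }
})

test_that("permutation-invariant observables are bit-identical after
           reduction", {
  spec <- reduced_argon_spec(48)
  run <- mc_run(spec, sim_config(n_steps = 20 * 480, equilibration_steps = 2000,
                                 output_stride = 480, seed = 5))
  traj <- run$trajectory
  red <- permutation_reduce(traj, get_frame(traj, 1))
  pair_dists <- function(pos, L) {
    n <- nrow(pos)
    out <- numeric(0)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      dx <- abs(pos[i, ] - pos[j, ])
      dx <- pmin(dx, L - dx)
      out <- c(out, sum(dx^2))
    }
    sort(out)
  }
  for (f in c(1L, n_frames(traj))) {
    a <- pair_dists(get_frame(traj, f), spec$box_length)
    b <- pair_dists(get_frame(red, f), spec$box_length)
    # the sorted multiset of squared pair distances (hence any radial
    # distribution histogram) is reproduced exactly, bit for bit
    expect_identical(a, b)
    # and energies agree to summation-order rounding
    expect_equal(total_energies(get_frame(red, f), spec)$U_vv,
                 total_energies(get_frame(traj, f), spec)$U_vv,
                 tolerance = 1e-12)
  }
})

test_that("reduction never increases the summed per-particle variance", {
  set.seed(31)
  base <- matrix(stats::runif(6 * 3, 0, 1.5), 6, 3)
  frames <- lapply(1:30, function(i) {
    p <- (base + stats::rnorm(18, 0, 0.15)) %% 1.5
    p[sample(6), ]   # scramble labels
  })
  traj <- toy_trajectory(frames, box = 1.5)
  red <- permutation_reduce(traj, base)
  sum_var <- function(tr) {
    sum(vapply(particle_clouds(tr), function(cl) sum(apply(cl, 2, stats::var)),
               0))
  }
  expect_lte(sum_var(red), sum_var(traj) + 1e-12)
})

test_that("reference selection is reproducible, distinct and bounded", {
  coords <- array(stats::runif(20 * 4 * 3), c(20, 4, 3))
  traj <- trajectory(coords, 1)
  r1 <- select_references(traj, 5, seed = 42)
  r2 <- select_references(traj, 5, seed = 42)
  expect_identical(r1$indices, r2$indices)
  expect_equal(length(unique(r1$indices)), 5)
  expect_equal(select_references(traj, 20, seed = 1)$indices, 1:20)
  expect_error(select_references(traj, 21), "exceeds")
})

test_that("reference-set estimation averages and spreads correctly", {
  coords <- array(stats::runif(10 * 3 * 3), c(10, 3, 3))
  traj <- trajectory(coords, 1)
  refs <- select_references(traj, 3, seed = 2)
  const <- estimate_with_references(traj, refs, function(tr) 7)
  expect_equal(const$value, 7)
  expect_equal(const$stderr, 0)
  one <- select_references(traj, 1, seed = 2)
  expect_warning(est <- estimate_with_references(traj, one, function(tr) 1.5),
                 "single reference")
  expect_equal(est$stderr, 0)
  # two references with hand-set values a, b
  vals <- c(0)
  fake <- local({
    i <- 0
    function(tr) { i <<- i + 1; c(3, 5)[i] }
  })
  two <- select_references(traj, 2, seed = 3)
  est2 <- estimate_with_references(traj, two, fake)
  expect_equal(est2$value, 4)
})

test_that("XYZ and GRO round-trips preserve coordinates and the box", {
  set.seed(6)
  coords <- array(stats::runif(3 * 5 * 3, 0, 1.5), c(3, 5, 3))
  traj <- trajectory(coords, 1.5)
  xyz <- tempfile(fileext = ".xyz")
  write_xyz(traj, xyz)
  back <- read_xyz(xyz)
  expect_equal(back$coords, traj$coords, tolerance = 1e-7)
  expect_equal(back$box, traj$box, tolerance = 1e-6)
  back_nm <- read_xyz(write_xyz(traj, tempfile(fileext = ".xyz"),
                                units = "nm"), units = "nm")
  expect_equal(back_nm$coords, traj$coords, tolerance = 1e-7)
  gro <- tempfile(fileext = ".gro")
  write_gro(traj, gro)
  bg <- read_gro(gro)
  expect_equal(bg$coords, traj$coords, tolerance = 1e-3)  # 3-decimal format
  expect_equal(bg$box, traj$box, tolerance = 1e-5)
  expect_equal(bg$species, traj$species)
  expect_equal(n_frames(bg), 3)
})
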
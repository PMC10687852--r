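test_that("pair mutual information matches enumeration oracles", {
  indep <- discrete_distribution(rep(0.25, 4), 2L)
  expect_equal(pair_mi_discrete(indep), 0, tolerance = 1e-12)
  correlated <- discrete_distribution(c(0.5, 0, 0, 0.5), 2L)
  expect_equal(pair_mi_discrete(correlated), log(2))
  # isolated ferromagnetic pair, J = 0.2: sum p ln(4p) by 4-state enumeration
  expect_equal(pair_mi_discrete(spin_pair_dist(0.2)), 0.01960699,
               tolerance = 1e-6)
  # symmetry and nonnegativity across random two-unit distributions
  set.seed(7)
  for (i in 1:10) {
    p <- stats::runif(4)
    d <- discrete_distribution(p / sum(p), 2L)
    expect_gte(pair_mi_discrete(d), -1e-10)
  }
  # inconsistent marginal violates the tower property
  bad <- discrete_distribution(c(0.9, 0.1), 1L)
  expect_error(pair_mi_discrete(spin_pair_dist(0.2), marg_a = bad),
               "inconsistent")
})

test_that("triple mutual information fixes the sign convention via XOR", {
  indep3 <- discrete_distribution(rep(1 / 8, 8), 3L)
  expect_equal(triple_mi_discrete(indep3), 0, tolerance = 1e-12)
  # XOR triple: I3 = -ln 2 and the order-3 expansion is exact (S = 2 ln 2)
  xor <- xor_triple_dist()
  expect_equal(triple_mi_discrete(xor), -log(2), tolerance = 1e-12)
  m <- mie_discrete(xor, order = 3)
  expect_equal(m$total, 2 * log(2), tolerance = 1e-12)
  expect_equal(m$total, exact_entropy(xor), tolerance = 1e-12)
  # one unit independent of a correlated pair: I3 = 0
  pair <- spin_pair_dist(0.4)
  joint <- discrete_distribution(c(pair$probs * 0.5, pair$probs * 0.5), 3L)
  expect_equal(triple_mi_discrete(joint), 0, tolerance = 1e-12)
})

test_that("the MIE is exact at order = system size and additive over
           independent units", {
  set.seed(11)
  for (i in 1:5) {
    p <- stats::runif(8)
    d <- discrete_distribution(p / sum(p), 3L)
    expect_equal(mie_discrete(d, order = 3)$total, exact_entropy(d),
                 tolerance = 1e-10)
  }
  two <- spin_pair_dist(0.6)
  expect_equal(mie_discrete(two, order = 2)$total, exact_entropy(two),
               tolerance = 1e-10)
  # product distribution: orders 1-3 all equal the sum of single entropies
  q <- c(0.3, 0.7)
  prod3 <- discrete_distribution(as.vector(outer(outer(q, q), q)), 3L)
  m3 <- mie_discrete(prod3, order = 3)
  expect_equal(m3$total, sum(m3$single_entropies), tolerance = 1e-12)
  expect_equal(m3$s_ge2, 0, tolerance = 1e-12)
  # appending an independent unit shifts the total by exactly its entropy
  base <- spin_pair_dist(0.3)
  h <- 0.5
  unit <- single_spin_dist(h)
  joint <- discrete_distribution(as.vector(outer(base$probs, unit$probs)), 3L)
  expect_equal(mie_discrete(joint, order = 3)$total,
               mie_discrete(base, order = 2)$total + exact_entropy(unit),
               tolerance = 1e-10)
})

test_that("kNN entropies recover closed-form Gaussian and uniform values", {
  set.seed(101)
  h1 <- knn_entropy(matrix(stats::rnorm(1e5), ncol = 1))
  expect_lt(abs(h1$value - 0.5 * log(2 * pi * exp(1))), 0.02)
  hu <- suppressWarnings(knn_entropy(matrix(stats::runif(1e5), ncol = 1)))
  expect_lt(abs(hu$value), 0.02)
  h3 <- knn_entropy(matrix(stats::rnorm(3e5), ncol = 3))
  expect_lt(abs(h3$value - 1.5 * log(2 * pi * exp(1))), 0.05)
  expect_equal(h3$method, "knn")
  expect_gt(h3$stderr, 0)
})

test_that("kNN estimator error on Gaussians shrinks monotonically with M", {
  truth <- 0.5 * log(2 * pi * exp(1))
  set.seed(33)
  rmse <- vapply(c(1e3, 1e4, 1e5), function(M) {
    errs <- vapply(1:10, function(i)
      knn_entropy(matrix(stats::rnorm(M), ncol = 1))$value - truth, 0)
    sqrt(mean(errs^2))
  }, 0)
  expect_true(all(diff(rmse) < 0))
})

test_that("periodic-metric entropy of a box-filling uniform cloud is ln V", {
  set.seed(5)
  L <- 2
  pts <- matrix(stats::runif(3 * 2e4, 0, L), ncol = 3)
  h <- knn_entropy(pts, box = L)
  expect_lt(abs(h$value - 3 * log(L)), 0.05)
})

test_that("kNN mutual information matches the bivariate-normal closed form", {
  set.seed(202)
  M <- 1e5
  x <- stats::rnorm(M)
  rho <- 0.5
  y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(M)
  mi <- pair_mi_knn(matrix(x), matrix(y))
  expect_lt(abs(mi$value - (-0.5 * log(1 - rho^2))), 0.02)
  z <- stats::rnorm(M)
  mi0 <- pair_mi_knn(matrix(x), matrix(z))
  expect_lt(abs(mi0$value), 0.01)
  # independent 3D clouds: estimate within 3 standard errors of zero
  a <- matrix(stats::rnorm(3e4 * 3), ncol = 3)
  b <- matrix(stats::rnorm(3e4 * 3), ncol = 3)
  mi3 <- pair_mi_knn(a, b)
  expect_lt(abs(mi3$value), max(3 * mi3$stderr, 0.02))
  expect_error(pair_mi_knn(a, b[1:10, ]), "match")
})

test_that("duplicate samples trigger the deterministic jitter fallback", {
  pts <- matrix(c(rep(0.5, 10), stats::runif(90)), ncol = 1)
  expect_warning(h <- knn_entropy(pts), "jitter")
  expect_true(is.finite(h$value))
  expect_warning(h2 <- knn_entropy(pts), "jitter")
  expect_identical(h$value, h2$value)  # jitter is deterministic
})

test_that("entropy unit conversion reproduces kB*T at 120 K", {
  expect_equal(nats_to_kjmol(1), 0.008314462618 * 120, tolerance = 1e-12)
  expect_equal(nats_to_kjmol(-2.5, 300), -2.5 * 0.008314462618 * 300)
})

test_that("continuous MIE recovers the Gaussian-dynamics pair correlation", {
  # two tethered particles, per-axis bivariate normal displacements with
  # correlation rho: closed-form I2 = -(3/2) ln(1 - rho^2)
  set.seed(77)
  M <- 4e5
  rho <- 0.6
  sd <- 0.05
  box <- 2
  c1 <- c(0.7, 1.0, 1.0)
  c2 <- c(1.3, 1.0, 1.0)
  u <- matrix(stats::rnorm(M * 3), ncol = 3)
  v <- rho * u + sqrt(1 - rho^2) * matrix(stats::rnorm(M * 3), ncol = 3)
  coords <- array(0, c(M, 2, 3))
  coords[, 1, ] <- sweep(sd * u, 2, c1, "+")
  coords[, 2, ] <- sweep(sd * v, 2, c2, "+")
  traj <- trajectory(coords, box)
  attr(traj, "reduced") <- TRUE
  m <- mie_continuous(traj, order = 2)
  expect_lt(abs(m$pair_mi$I2[1] - (-1.5 * log(1 - rho^2))), 0.03)
  # order 1 equals the sum of per-particle cloud entropies by definition
  m1 <- mie_continuous(traj, order = 1)
  cl <- particle_clouds(traj)
  expect_equal(sum(m1$single_entropies),
               knn_entropy(cl[[1]], box = box)$value +
               knn_entropy(cl[[2]], box = box)$value,
               tolerance = 1e-12)
})

test_that("an ideal-gas trajectory shows no pair information", {
  # independent uniform clouds: every I2 is pure estimator noise
  set.seed(88)
  M <- 4000
  coords <- array(stats::runif(M * 4 * 3, 0, 1.5), c(M, 4, 3))
  traj <- trajectory(coords, 1.5)
  attr(traj, "reduced") <- TRUE
  m <- mie_continuous(traj, order = 2)
  expect_lt(abs(sum(m$pair_mi$I2)) / nrow(m$pair_mi), 0.03)
})
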
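# shared fixtures, built in code

# a single free spin in field h: 1x1 "lattice" cannot use lattice_spec
# (side >= 3), so build the 2-state distribution directly
single_spin_dist <- function(h, beta = 1) {
  w <- exp(beta * h * c(-1, 1))  # state code 0 -> spin -1, code 1 -> spin +1
  discrete_distribution(w / sum(w), 1L)
}

# isolated ferromagnetic pair: H = -J s1 s2
spin_pair_dist <- function(J, beta = 1) {
  s <- state_spins(0:3, 2L)
  w <- exp(beta * J * s[, 1] * s[, 2])
  discrete_distribution(w / sum(w), 2L)
}

# XOR triple: units 1, 2 uniform, unit 3 = parity (product) of the first two
xor_triple_dist <- function() {
  s <- state_spins(0:7, 3L)
  p <- ifelse(s[, 3] == s[, 1] * s[, 2], 0.25, 0)
  discrete_distribution(p, 3L)
}

# tiny deterministic trajectory builder
toy_trajectory <- function(frames, box = 2) {
  coords <- array(0, c(length(frames), nrow(frames[[1]]), 3))
  for (f in seq_along(frames)) coords[f, , ] <- frames[[f]]
  trajectory(coords, box)
}

# brute-force minimal assignment by enumerating all n! permutations
brute_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL
  best_c <- Inf
  for (p in perms(seq_len(n))) {
    cc <- sum(cost[cbind(seq_len(n), p)])
    if (cc < best_c) { best_c <- cc; best <- p }
  }
  list(perm = best, cost = best_c)
}

kT120 <- 0.008314462618 * 120
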
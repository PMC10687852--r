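# Continuous (trajectory-based) mutual information expansion: single-body
# entropies from the 3D per-particle sample clouds, pairwise mutual
# information over all particle pairs, and triple terms restricted to
# triples whose mean pairwise minimum-image distance is below a cutoff.
# All entropies are Kozachenko-Leonenko kNN estimates in nats.

#' Per-particle sample clouds of a trajectory
#'
#' @param traj A \code{trajectory}.
#' @return List of M x 3 matrices, one per particle (M = number of frames).
#' @export
particle_clouds <- function(traj) {
  lapply(seq_len(n_particles(traj)), function(p)
    matrix(traj$coords[, p, ], ncol = 3))
}

# gap-cut unwrap of one periodic cloud: cut each dimension's period at its
# widest empty circular gap (see knn_entropy); returns the unwrapped
# coordinates and the smallest gap, which bounds the distances for which
# plain Euclidean equals minimum-image
unwrap_cloud <- function(cl, per) {
  gmin <- Inf
  for (j in seq_len(ncol(cl))) {
    L <- per[j]
    x <- cl[, j] %% L
    s <- sort(x)
    gap <- c(diff(s), s[1] + L - s[length(s)])
    gi <- which.max(gap)
    gmin <- min(gmin, gap[gi])
    cut <- s[gi] + gap[gi] / 2   # gap midpoint (wrap-around included)
    cl[, j] <- (x - cut) %% L
  }
  list(un = cl, gmin = gmin)
}

# k-th NN distances of a periodic cloud given its unwrapped form; exact
# (falls back to the direct minimum-image scan if any distance approaches
# the gap bound)
knn_r_periodic <- function(orig, un, gmin, k, per) {
  r <- knn_dist_cpp(un, as.integer(k))
  if (all(r < 0.95 * gmin)) return(r)
  knn_dist_periodic_cpp(orig, as.integer(k), per)
}

kl_entropy_from_r <- function(r, M, d, k) {
  if (any(r == 0)) return(NA_real_)  # caller re-runs via knn_entropy jitter
  digamma(M) - digamma(k) + (d / 2) * log(pi) - lgamma(d / 2 + 1) +
    mean(d * log(r))
}

pair_mean_dists <- function(clouds, box3) {
  n <- length(clouds)
  pr <- utils::combn(n, 2)
  d <- vapply(seq_len(ncol(pr)), function(ix)
    mean_pair_distance_cpp(clouds[[pr[1, ix]]], clouds[[pr[2, ix]]], box3), 0)
  list(pairs = pr, dists = d, key = paste(pr[1, ], pr[2, ]))
}

#' Select particle triples by mean pairwise distance
#'
#' Returns the triples whose mean pairwise minimum-image distance (averaged
#' over frames and over the three pairs) is below the cutoff.  When
#' differencing MIE entropies between two systems, evaluate both over the
#' union of their selections so that every triple term appears in both sums
#' and its estimator bias cancels.
#'
#' @param traj A \code{trajectory} (ideally permutation-reduced).
#' @param triple_cutoff Cutoff in nm (default 0.5).
#' @return Integer matrix with 3 rows, one column per selected triple.
#' @export
select_triples <- function(traj, triple_cutoff = 0.5) {
  pd <- pair_mean_dists(particle_clouds(traj), traj$box)
  triples_below(pd, n_particles(traj), triple_cutoff)
}

triples_below <- function(pd, n, cutoff) {
  tr <- utils::combn(n, 3)
  tmean <- (pd$dists[match(paste(tr[1, ], tr[2, ]), pd$key)] +
            pd$dists[match(paste(tr[1, ], tr[3, ]), pd$key)] +
            pd$dists[match(paste(tr[2, ], tr[3, ]), pd$key)]) / 3
  tr[, tmean < cutoff, drop = FALSE]
}

#' Union of two triple selections
#'
#' @param a,b Integer matrices with 3 rows (as from
#'   \code{\link{select_triples}}).
#' @return Combined matrix without duplicate columns.
#' @export
union_triples <- function(a, b) {
  m <- cbind(a, b)
  m[, !duplicated(paste(m[1, ], m[2, ], m[3, ])), drop = FALSE]
}

#' Mutual information expansion of a particle trajectory
#'
#' Estimates the configurational entropy of the solvent as
#' \eqn{\sum_i S_1(i) - \sum_{j<k} I_2(j,k) + \sum I_3}, with every term a
#' kNN entropy estimate under the minimum-image periodic metric of the
#' trajectory box.  The trajectory should be permutation-reduced first
#' (\code{\link{permutation_reduce}}); otherwise particle labels are
#' arbitrary, the per-label clouds fill the box, and the expansion loses its
#' meaning (a warning is emitted).
#'
#' @param traj A \code{trajectory} (solvent particles only; an immobilized
#'   solute has no configurational entropy and is never a unit).
#' @param order Truncation order: 1, 2 or 3.
#' @param triple_cutoff Mean-pairwise-distance cutoff (nm) selecting the
#'   triples retained at order 3 (default 0.5).
#' @param k Neighbour rank of the kNN estimator (default 1).
#' @param pair_cutoff Optional distance cutoff restricting pairs as well;
#'   default NULL keeps all pairs.
#' @param triples Optional explicit triple set (3-row integer matrix)
#'   overriding the cutoff-based selection, e.g. a
#'   \code{\link{union_triples}} of two systems' selections.
#' @return Object of class \code{mie_result} (entropies in nats); pair and
#'   triple tables carry the per-term estimates.
#' @export
mie_continuous <- function(traj, order = 3, triple_cutoff = 0.5, k = 1,
                           pair_cutoff = NULL, triples = NULL) {
  stopifnot(inherits(traj, "trajectory"), order %in% 1:3)
  if (!isTRUE(attr(traj, "reduced")))
    warning("trajectory is not permutation-reduced; MIE terms are label-dependent")
  box3 <- traj$box
  clouds <- particle_clouds(traj)
  n <- length(clouds)
  M <- n_frames(traj)
  un <- lapply(clouds, unwrap_cloud, per = box3)
  joint_entropy <- function(units) {
    d <- 3 * length(units)
    orig <- do.call(cbind, clouds[units])
    uw <- do.call(cbind, lapply(un[units], `[[`, "un"))
    gmin <- min(vapply(un[units], `[[`, 0, "gmin"))
    r <- knn_r_periodic(orig, uw, gmin, k, rep(box3, length(units)))
    h <- kl_entropy_from_r(r, M, d, k)
    if (is.na(h)) h <- knn_entropy(orig, k, rep(box3, length(units)))$value
    h
  }
  s1 <- vapply(seq_len(n), function(i) joint_entropy(i), 0)
  pair_df <- data.frame(j = integer(), k = integer(), I2 = numeric())
  triple_df <- data.frame(l = integer(), m = integer(), n = integer(),
                          I3 = numeric())
  if (order >= 2 && n >= 2) {
    pd <- pair_mean_dists(clouds, box3)
    pr <- pd$pairs
    keep <- if (is.null(pair_cutoff)) rep(TRUE, ncol(pr))
            else pd$dists < pair_cutoff
    sj <- rep(NA_real_, ncol(pr))
    sj[keep] <- vapply(which(keep), function(ix)
      joint_entropy(c(pr[1, ix], pr[2, ix])), 0)
    I2 <- rep(0, ncol(pr))
    I2[keep] <- s1[pr[1, keep]] + s1[pr[2, keep]] - sj[keep]
    pair_df <- data.frame(j = pr[1, ], k = pr[2, ], I2 = I2,
                          mean_dist = pd$dists, included = keep)
    if (order >= 3 && n >= 3) {
      if (is.null(triples)) triples <- triples_below(pd, n, triple_cutoff)
      nt <- ncol(triples)
      I3 <- numeric(nt)
      for (q in seq_len(nt)) {
        ix <- triples[, q]
        s3 <- joint_entropy(ix)
        pk <- match(c(paste(ix[1], ix[2]), paste(ix[1], ix[3]),
                      paste(ix[2], ix[3])), pd$key)
        s2 <- sj[pk]
        if (anyNA(s2))  # pair entropies skipped by pair_cutoff
          s2[is.na(s2)] <- vapply(pk[is.na(s2)], function(p)
            joint_entropy(c(pr[1, p], pr[2, p])), 0)
        I3[q] <- sum(s1[ix]) - sum(s2) + s3
      }
      if (nt)
        triple_df <- data.frame(l = triples[1, ], m = triples[2, ],
                                n = triples[3, ], I3 = I3)
    }
  }
  total <- sum(s1) - sum(pair_df$I2) + sum(triple_df$I3)
  structure(list(single_entropies = s1, pair_mi = pair_df,
                 triple_mi = triple_df, order = order, total = total,
                 s_ge2 = total - sum(s1)),
            class = "mie_result")
}
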
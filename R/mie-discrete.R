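# Mutual information expansion (MIE) of a discrete joint entropy:
#   S = sum_i S1(i) - sum_{j<k} I2(j,k) + sum_{l<m<n} I3(l,m,n) - ...
# truncated here at order 3.  I2(j,k) = S(j) + S(k) - S(j,k);
# I3(l,m,n) = S(l)+S(m)+S(n) - S(l,m)-S(l,n)-S(m,n) + S(l,m,n)
# (interaction-information convention, fixed so the alternating sum is exact
# for a 3-unit system).

check_marginal <- function(joint, sites, given, tol = 1e-8) {
  if (is.null(given)) return(marginalize(joint, sites))
  direct <- marginalize(joint, sites)
  if (max(abs(direct$probs - given$probs)) > tol)
    stop("supplied marginal is inconsistent with the joint distribution")
  given
}

#' Two-body mutual information of a discrete joint distribution
#'
#' \eqn{I_2(A, B) = S(A) + S(B) - S(A, B)} in nats; nonnegative and symmetric.
#'
#' @param joint A \code{discrete_distribution} over 2 units.
#' @param marg_a,marg_b Optional single-unit marginals; derived from
#'   \code{joint} when omitted, validated against it (tower property) when
#'   supplied.
#' @return Mutual information in nats.
#' @export
pair_mi_discrete <- function(joint, marg_a = NULL, marg_b = NULL) {
  stopifnot(inherits(joint, "discrete_distribution"), joint$n_units == 2L)
  marg_a <- check_marginal(joint, 1L, marg_a)
  marg_b <- check_marginal(joint, 2L, marg_b)
  exact_entropy(marg_a) + exact_entropy(marg_b) - exact_entropy(joint)
}

#' Three-body mutual information (interaction information)
#'
#' \eqn{I_3 = \sum_i S(i) - \sum_{i<j} S(i,j) + S(1,2,3)}; symmetric in its
#' units and may be negative.  With this sign convention the order-3 MIE
#' \eqn{\sum S_1 - \sum I_2 + \sum I_3} is exact for a 3-unit system.
#'
#' @param joint A \code{discrete_distribution} over 3 units.
#' @param marginals Optional named list with elements \code{s1} (list of 3
#'   single-unit marginals) and \code{s2} (list of 3 pair marginals in the
#'   order (1,2), (1,3), (2,3)); validated against \code{joint} when supplied.
#' @return Interaction information in nats.
#' @export
triple_mi_discrete <- function(joint, marginals = NULL) {
  stopifnot(inherits(joint, "discrete_distribution"), joint$n_units == 3L)
  ones <- list(1L, 2L, 3L)
  twos <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  s1 <- vapply(seq_len(3), function(i)
    exact_entropy(check_marginal(joint, ones[[i]], marginals$s1[[i]])), 0)
  s2 <- vapply(seq_len(3), function(i)
    exact_entropy(check_marginal(joint, twos[[i]], marginals$s2[[i]])), 0)
  sum(s1) - sum(s2) + exact_entropy(joint)
}

#' Mutual information expansion of a discrete distribution
#'
#' Decomposes the joint entropy of the selected units into single-body
#' entropies and pair/triple correlation terms, truncated at \code{order}.
#' The truncation is exact when \code{length(units) <= order}.
#'
#' @param dist A \code{discrete_distribution}.
#' @param units Unit indices to expand over (default all).
#' @param order Truncation order: 1, 2 or 3.
#' @return Object of class \code{mie_result}: list with
#'   \code{single_entropies}, \code{pair_mi} (data frame j, k, I2),
#'   \code{triple_mi} (data frame l, m, n, I3), \code{order}, \code{total}
#'   (the truncated MIE entropy) and \code{s_ge2 = total - sum(S1)}.
#' @export
mie_discrete <- function(dist, units = seq_len(dist$n_units), order = 3) {
  stopifnot(inherits(dist, "discrete_distribution"))
  if (!order %in% 1:3) stop("order must be 1, 2 or 3 (higher orders unsupported)")
  units <- as.integer(units)
  if (length(units) < order) stop("need at least `order` units")
  nu <- length(units)
  s1 <- vapply(units, function(i) exact_entropy(marginalize(dist, i)), 0)
  names(s1) <- units
  pair_df <- data.frame(j = integer(), k = integer(), I2 = numeric())
  triple_df <- data.frame(l = integer(), m = integer(), n = integer(),
                          I3 = numeric())
  s2 <- NULL
  if (order >= 2 && nu >= 2) {
    pr <- utils::combn(nu, 2)
    s2 <- apply(pr, 2, function(ix)
      exact_entropy(marginalize(dist, units[ix])))
    I2 <- s1[pr[1, ]] + s1[pr[2, ]] - s2
    pair_df <- data.frame(j = units[pr[1, ]], k = units[pr[2, ]], I2 = I2)
  }
  if (order >= 3 && nu >= 3) {
    pr <- utils::combn(nu, 2)
    pkey <- paste(pr[1, ], pr[2, ])
    tr <- utils::combn(nu, 3)
    I3 <- apply(tr, 2, function(ix) {
      s3 <- exact_entropy(marginalize(dist, units[ix]))
      pk <- match(c(paste(ix[1], ix[2]), paste(ix[1], ix[3]),
                    paste(ix[2], ix[3])), pkey)
      sum(s1[ix]) - sum(s2[pk]) + s3
    })
    triple_df <- data.frame(l = units[tr[1, ]], m = units[tr[2, ]],
                            n = units[tr[3, ]], I3 = I3)
  }
  total <- sum(s1) - sum(pair_df$I2) + sum(triple_df$I3)
  structure(list(single_entropies = s1, pair_mi = pair_df,
                 triple_mi = triple_df, order = order, total = total,
                 s_ge2 = total - sum(s1)),
            class = "mie_result")
}

#' @export
print.mie_result <- function(x, ...) {
  cat(sprintf("MIE (order %d): total S = %.4f nats\n", x$order, x$total))
  cat(sprintf("  sum S1 = %.4f  (%d units)\n", sum(x$single_entropies),
              length(x$single_entropies)))
  if (nrow(x$pair_mi)) cat(sprintf("  sum I2 = %.4f  (%d pairs)\n",
                                   sum(x$pair_mi$I2), nrow(x$pair_mi)))
  if (nrow(x$triple_mi)) cat(sprintf("  sum I3 = %.4f  (%d triples)\n",
                                     sum(x$triple_mi$I3), nrow(x$triple_mi)))
  cat(sprintf("  S_>=2  = %.4f\n", x$s_ge2))
  invisible(x)
}
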
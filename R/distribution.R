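#' Discrete probability distribution over binary-unit states
#'
#' A normalized distribution over the joint states of \code{n_units} binary
#' units (spins).  States are identified by integer codes \code{0} to
#' \code{2^n_units - 1}; unit \code{i} takes the value \code{+1} when bit
#' \code{i - 1} of the code is set and \code{-1} otherwise (row-major site
#' order for lattice systems).
#'
#' @param probs Numeric vector of length \code{2^n_units}, nonnegative,
#'   summing to 1 (within \code{1e-12}; renormalized exactly).
#' @param n_units Number of binary units.
#' @param log_weights Optional unnormalized log weights the probabilities were
#'   derived from (kept for reference).
#' @return An object of class \code{discrete_distribution} with elements
#'   \code{support} (integer codes), \code{probs}, \code{n_units} and
#'   optionally \code{log_weights}.
#' @export
discrete_distribution <- function(probs, n_units, log_weights = NULL) {
  n_units <- as.integer(n_units)
  stopifnot(n_units >= 1, length(probs) == 2^n_units)
  if (any(probs < -1e-15)) stop("probabilities must be nonnegative")
  probs <- pmax(probs, 0)
  tot <- sum(probs)
  if (abs(tot - 1) > 1e-12 && abs(tot - 1) > 1e-8)
    stop("probabilities must sum to 1")
  structure(
    list(support = seq_along(probs) - 1L, probs = probs / tot,
         n_units = n_units, log_weights = log_weights),
    class = "discrete_distribution")
}

#' @export
print.discrete_distribution <- function(x, ...) {
  cat(sprintf("discrete_distribution: %d binary units, %d states, S = %.4f nats\n",
              x$n_units, length(x$probs), exact_entropy(x)))
  invisible(x)
}

#' Decode state codes into a spin matrix
#'
#' @param codes Integer state codes.
#' @param n_units Number of binary units.
#' @return Integer matrix (\code{length(codes)} x \code{n_units}) of -1/+1
#'   values; column \code{i} is unit \code{i} (bit \code{i - 1}).
#' @export
state_spins <- function(codes, n_units) {
  out <- matrix(-1L, length(codes), n_units)
  for (i in seq_len(n_units)) {
    set <- bitwAnd(codes, bitwShiftL(1L, i - 1L)) != 0L
    out[set, i] <- 1L
  }
  out
}

#' Gibbs-Shannon entropy of a discrete distribution (nats)
#'
#' \eqn{S = -\sum_x P(x) \ln P(x)}, with the convention
#' \eqn{0 \ln 0 = 0}.
#'
#' @param dist A \code{discrete_distribution}.
#' @return Entropy in nats; between 0 and \code{ln(#states)}.
#' @export
exact_entropy <- function(dist) {
  stopifnot(inherits(dist, "discrete_distribution"))
  p <- dist$probs[dist$probs > 0]
  -sum(p * log(p))
}

#' Ensemble average of an observable
#'
#' @param dist A \code{discrete_distribution}.
#' @param observable Either a numeric vector with one value per support state,
#'   or a function taking the decoded spin matrix (states x units, values
#'   -1/+1) and returning one value per state.
#' @return The probability-weighted mean.
#' @export
ensemble_average <- function(dist, observable) {
  stopifnot(inherits(dist, "discrete_distribution"))
  if (is.function(observable))
    observable <- observable(state_spins(dist$support, dist$n_units))
  if (length(observable) != length(dist$probs))
    stop("observable must be defined on every support state")
  sum(dist$probs * observable)
}

#' Marginal distribution over a subset of units
#'
#' Sums the joint probabilities over all units not in \code{sites}.  The
#' marginal's unit \code{j} corresponds to \code{sites[j]} (bit \code{j - 1}
#' of the marginal state code).
#'
#' @param dist A \code{discrete_distribution}.
#' @param sites Distinct unit indices (1-based) to retain.
#' @return A \code{discrete_distribution} over \code{length(sites)} units.
#' @export
marginalize <- function(dist, sites) {
  stopifnot(inherits(dist, "discrete_distribution"))
  sites <- as.integer(sites)
  if (anyDuplicated(sites)) stop("repeated site indices")
  if (any(sites < 1L | sites > dist$n_units)) stop("site index out of range")
  code <- integer(length(dist$support))
  for (j in seq_along(sites)) {
    bit <- bitwAnd(dist$support, bitwShiftL(1L, sites[j] - 1L)) != 0L
    code <- code + bitwShiftL(1L, j - 1L) * as.integer(bit)
  }
  m <- numeric(2^length(sites))
  agg <- rowsum(dist$probs, code)
  m[as.integer(rownames(agg)) + 1L] <- agg
  discrete_distribution(m, length(sites))
}
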
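#' Ising solvation-model specification
#'
#' A periodic L x L Ising lattice of "solvent" spins with ferromagnetic
#' nearest-neighbour coupling \code{J}.  A solute is represented implicitly by
#' an external field of strength \code{lambda * field_max} acting on the
#' "solvation shell" (by default the central 2x2 block of spins), with a
#' per-site sign pattern.  With the default staggered pattern
#' \code{(+1, -1, -1, +1)} the model is gauge-equivalent (checkerboard flip on
#' the bipartite lattice) to an antiferromagnet in a uniform field.
#'
#' Conventions: \eqn{H_{vv} = -J \sum_{<ij>} \sigma_i \sigma_j} over
#' nearest-neighbour bonds and
#' \eqn{H_{uv}(\lambda) = -\lambda\, h \sum_{s \in \mathrm{shell}}
#' \mathrm{sign}_s\, \sigma_s} with \eqn{h =} \code{field_max}.  All energies
#' are unitless with \eqn{k_B = T = \beta = 1} by default.
#'
#' @param side_length Lattice side L (>= 3 so periodic bonds are simple edges).
#' @param coupling_J Nearest-neighbour coupling (default 0.2, subcritical).
#' @param beta Inverse temperature (default 1).
#' @param shell_sites 1-based row-major site indices of the solvation shell;
#'   default the central 2x2 block.
#' @param field_signs Per-shell-site sign in \{+1, -1\}; default staggered.
#' @param field_max Field magnitude per unit spin at full coupling (default 4).
#' @return An object of class \code{lattice_spec}.
#' @export
lattice_spec <- function(side_length = 4L, coupling_J = 0.2, beta = 1,
                         shell_sites = NULL, field_signs = c(1, -1, -1, 1),
                         field_max = 4) {
  side_length <- as.integer(side_length)
  if (side_length < 3L)
    stop("side_length must be >= 3 (periodic bonds double-count otherwise)")
  if (field_max < 0) stop("field_max must be >= 0")
  if (is.null(shell_sites)) {
    # central 2x2 block, row-major 1-based: rows/cols floor(L/2)-? use rows
    # (L/2, L/2+1) for even L, centered for odd L
    r0 <- floor((side_length - 2) / 2)
    shell_sites <- as.integer(c(
      r0 * side_length + r0 + 1, r0 * side_length + r0 + 2,
      (r0 + 1) * side_length + r0 + 1, (r0 + 1) * side_length + r0 + 2))
  }
  shell_sites <- as.integer(shell_sites)
  if (anyDuplicated(shell_sites)) stop("shell_sites must be distinct")
  if (length(field_signs) != length(shell_sites))
    stop("field_signs must match shell_sites")
  if (!all(field_signs %in% c(-1, 1))) stop("field_signs must be +1 or -1")
  structure(
    list(side_length = side_length, coupling_J = coupling_J, beta = beta,
         shell_sites = shell_sites, field_signs = field_signs,
         field_max = field_max),
    class = "lattice_spec")
}

#' @export
print.lattice_spec <- function(x, ...) {
  cat(sprintf(paste0("lattice_spec: %dx%d periodic, J = %g, beta = %g, ",
                     "field_max = %g, signs (%s) on sites (%s)\n"),
              x$side_length, x$side_length, x$coupling_J, x$beta, x$field_max,
              paste(x$field_signs, collapse = ","),
              paste(x$shell_sites, collapse = ",")))
  invisible(x)
}

#' Nearest-neighbour bond list of the periodic lattice
#'
#' @param spec A \code{lattice_spec}.
#' @return Integer matrix with two columns; each unordered nearest-neighbour
#'   pair under periodic boundaries appears exactly once (2 L^2 rows).
#' @export
bond_list <- function(spec) {
  L <- spec$side_length
  site <- function(r, c) ((r %% L) * L + (c %% L)) + 1L
  n <- L * L
  b <- matrix(0L, 2L * n, 2L)
  k <- 1L
  for (r in 0:(L - 1)) for (cc in 0:(L - 1)) {
    b[k, ] <- c(site(r, cc), site(r, cc + 1)); k <- k + 1L
    b[k, ] <- c(site(r, cc), site(r + 1, cc)); k <- k + 1L
  }
  b
}

# cache of enumerated spin matrices keyed by site count
.solvdecomp_cache <- new.env(parent = emptyenv())

#' Enumerate all spin configurations
#'
#' @param n_sites Number of spins (<= 20).
#' @return Integer matrix (2^n_sites x n_sites) of -1/+1 values; row k is the
#'   state with code k-1 (spin i = +1 iff bit i-1 set).
#' @export
enumerate_states <- function(n_sites) {
  n_sites <- as.integer(n_sites)
  if (n_sites > 20L) stop("state space too large to enumerate (n_sites > 20)")
  key <- as.character(n_sites)
  if (!is.null(.solvdecomp_cache[[key]])) return(.solvdecomp_cache[[key]])
  S <- state_spins(0:(2^n_sites - 1L), n_sites)
  .solvdecomp_cache[[key]] <- S
  S
}

as_spin_matrix <- function(config, n) {
  if (is.matrix(config)) m <- config else m <- matrix(config, nrow = 1)
  if (ncol(m) != n) stop("configuration has wrong number of spins")
  if (!all(m == 1L | m == -1L)) stop("spins must be exactly +1 or -1")
  m
}

#' Solvent-solvent energy of spin configurations
#'
#' \eqn{H_{vv} = -J \sum_{<ij>} \sigma_i \sigma_j}.
#'
#' @param config Spin vector (length L^2) or matrix (states x L^2) of -1/+1.
#' @param spec A \code{lattice_spec}.
#' @return Energy (one value per configuration).
#' @export
energy_vv <- function(config, spec) {
  n <- spec$side_length^2
  m <- as_spin_matrix(config, n)
  b <- bond_list(spec)
  e <- -spec$coupling_J * rowSums(m[, b[, 1], drop = FALSE] *
                                  m[, b[, 2], drop = FALSE])
  if (!is.matrix(config)) e[1] else e
}

#' Solute-solvent (field) energy of spin configurations
#'
#' \eqn{H_{uv}(\lambda) = -\lambda\, h \sum_s \mathrm{sign}_s \sigma_s} over
#' the shell sites; linear in \code{lambda} and zero at \code{lambda = 0}.
#'
#' @param config Spin vector or matrix of -1/+1.
#' @param lambda Coupling parameter in [0, 1].
#' @param spec A \code{lattice_spec}.
#' @return Energy (one value per configuration).
#' @export
energy_uv <- function(config, lambda, spec) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  n <- spec$side_length^2
  m <- as_spin_matrix(config, n)
  f <- rowSums(sweep(m[, spec$shell_sites, drop = FALSE], 2,
                     spec$field_signs, "*"))
  e <- -lambda * spec$field_max * f
  if (!is.matrix(config)) e[1] else e
}

# per-state shell-field sum f(x) = sum_s sign_s sigma_s over all states
shell_field_all <- function(spec) {
  S <- enumerate_states(spec$side_length^2)
  rowSums(sweep(S[, spec$shell_sites, drop = FALSE], 2, spec$field_signs, "*"))
}

energy_vv_all <- function(spec) {
  S <- enumerate_states(spec$side_length^2)
  b <- bond_list(spec)
  -spec$coupling_J * rowSums(S[, b[, 1]] * S[, b[, 2]])
}

#' Exact Boltzmann distribution of the Ising solvation model
#'
#' Enumerates all \code{2^(L^2)} states and returns
#' \eqn{P(x) \propto \exp(-\beta [H_{vv}(x) + H_{uv}(x; \lambda)])}.
#'
#' @param spec A \code{lattice_spec} with \code{side_length^2 <= 20}.
#' @param lambda Coupling parameter in [0, 1].
#' @return A \code{discrete_distribution} over all states.
#' @export
boltzmann_distribution <- function(spec, lambda = 1) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  n <- spec$side_length^2
  if (n > 20L) stop("state space too large to enumerate (L^2 > 20)")
  lw <- -spec$beta * (energy_vv_all(spec) -
                      lambda * spec$field_max * shell_field_all(spec))
  w <- exp(lw - max(lw))
  discrete_distribution(w / sum(w), n, log_weights = lw)
}

# Factorized per-lambda machinery: the Boltzmann weight separates as
# w_lambda(x) = w0(x) * exp(beta * lambda * field_max * f(x)) with f taking
# only a handful of values, so marginals across a whole lambda grid reduce to
# small (2^k x #levels) tables contracted against exp(beta lambda h f_level).
ising_lambda_tables <- function(spec, subsets) {
  n <- spec$side_length^2
  S <- enumerate_states(n)
  hvv <- energy_vv_all(spec)
  f <- shell_field_all(spec)
  w0 <- exp(-spec$beta * hvv)
  flev <- sort(unique(f))
  fi <- match(f, flev)
  nl <- length(flev)
  tabs <- lapply(subsets, function(sites) {
    code <- integer(length(w0))
    for (j in seq_along(sites))
      code <- code + bitwShiftL(1L, j - 1L) *
        as.integer(S[, sites[j]] == 1L)
    agg <- rowsum(w0, code * nl + (fi - 1L))
    key <- as.integer(rownames(agg))
    Tm <- matrix(0, 2^length(sites), nl)
    Tm[cbind(key %/% nl + 1L, key %% nl + 1L)] <- agg
    Tm
  })
  # (H_vv, f) cells for exact per-lambda entropy and averages
  cell <- paste(hvv, f)
  uc <- unique(cell)
  ci <- match(cell, uc)
  first <- match(uc, cell)
  list(tabs = tabs, flev = flev,
       cell_w = as.vector(rowsum(w0, ci)),
       cell_n = as.vector(rowsum(rep(1, length(ci)), ci)),
       cell_h = hvv[first], cell_f = f[first])
}

plogp_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# exact S, <H_vv>, <H_uv>, <dH/dlambda> at one lambda from the cell tables
ising_cell_stats <- function(tb, spec, lambda) {
  a <- spec$beta * lambda * spec$field_max
  wc <- tb$cell_w * exp(a * tb$cell_f)
  Z <- sum(wc)
  pc <- wc / Z
  # states inside a cell share identical probability pc/cell_n
  S <- -sum(pc * (log(pc) - log(tb$cell_n)))
  list(S = S,
       mean_vv = sum(pc * tb$cell_h),
       mean_uv_base = sum(pc * (-spec$field_max * tb$cell_f)),
       Z = Z)
}

#' Exact per-lambda entropy and MIE curves of the Ising model
#'
#' For every value of the coupling grid, computes the exact entropy, the
#' order-1 MIE total (sum of single-site marginal entropies) and, if
#' \code{order >= 2}, the order-2 and order-3 MIE totals over all site pairs
#' and triples.  Uses the factorized structure of the Boltzmann weights so the
#' whole 251-point scan runs in seconds.
#'
#' @param spec A \code{lattice_spec}.
#' @param lambda_values Coupling grid in [0, 1].
#' @param order Truncation order of the MIE curves (1, 2 or 3).
#' @return Data frame with columns \code{lambda}, \code{S_exact}, \code{S1},
#'   and (order permitting) \code{S_mie2}, \code{S_mie3}.
#' @export
ising_mie_curve <- function(spec, lambda_values = lambda_grid(251),
                            order = 3) {
  stopifnot(order %in% 1:3)
  n <- spec$side_length^2
  sites <- seq_len(n)
  singles <- as.list(sites)
  pairs <- if (order >= 2) utils::combn(n, 2, simplify = FALSE) else list()
  triples <- if (order >= 3) utils::combn(n, 3, simplify = FALSE) else list()
  tb <- ising_lambda_tables(spec, c(singles, pairs, triples))
  i1 <- seq_along(singles)
  i2 <- length(singles) + seq_along(pairs)
  i3 <- length(singles) + length(pairs) + seq_along(triples)
  pair_key <- vapply(pairs, paste, "", collapse = ",")
  out <- lapply(lambda_values, function(l) {
    ev <- exp(spec$beta * l * spec$field_max * tb$flev)
    st <- ising_cell_stats(tb, spec, l)
    ents <- vapply(tb$tabs, function(Tm) {
      plogp_entropy(as.vector(Tm %*% ev) / st$Z)
    }, 0)
    S1 <- ents[i1]
    row <- c(lambda = l, S_exact = st$S, S1 = sum(S1))
    if (order >= 2) {
      S2 <- ents[i2]
      I2 <- vapply(seq_along(pairs), function(k) {
        p <- pairs[[k]]; S1[p[1]] + S1[p[2]] - S2[k]
      }, 0)
      row <- c(row, S_mie2 = sum(S1) - sum(I2))
      if (order >= 3) {
        S3 <- ents[i3]
        I3 <- vapply(seq_along(triples), function(k) {
          tr <- triples[[k]]
          pk <- c(match(paste(tr[1], tr[2], sep = ","), pair_key),
                  match(paste(tr[1], tr[3], sep = ","), pair_key),
                  match(paste(tr[2], tr[3], sep = ","), pair_key))
          sum(S1[tr]) - sum(S2[pk]) + S3[k]
        }, 0)
        row <- c(row, S_mie3 = sum(S1) - sum(I2) + sum(I3))
      }
    }
    row
  })
  as.data.frame(do.call(rbind, out))
}
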
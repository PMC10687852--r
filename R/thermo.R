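#' Equidistant coupling-parameter grid
#'
#' @param n Number of grid points (default 251).
#' @return Strictly increasing numeric vector from 0 to 1.
#' @export
lambda_grid <- function(n = 251) {
  n <- as.integer(n)
  stopifnot(n >= 2)
  seq(0, 1, length.out = n)
}

validate_lambda_grid <- function(lambda) {
  if (length(lambda) < 2 || any(diff(lambda) <= 0))
    stop("lambda grid must be strictly increasing")
  if (abs(lambda[1]) > 1e-12 || abs(lambda[length(lambda)] - 1) > 1e-12)
    stop("lambda grid must span [0, 1]")
  invisible(lambda)
}

#' Per-lambda ensemble-average curve for thermodynamic integration
#'
#' Collects the per-window averages entering the canonical decomposition:
#' the TI integrand \eqn{\langle \partial H / \partial \lambda \rangle},
#' the solute-solvent energy \eqn{\langle H_{uv}(\lambda) \rangle} and the
#' solvent-solvent energy \eqn{\langle H_{vv} \rangle}.  Sampled systems may
#' attach standard errors and exactly enumerable systems the exact entropy.
#'
#' @param lambda Strictly increasing grid spanning [0, 1].
#' @param mean_uv_base Per-lambda \eqn{\langle \partial H/\partial\lambda \rangle}.
#' @param mean_uv Per-lambda \eqn{\langle H_{uv}(\lambda) \rangle}; defaults to
#'   \code{lambda * mean_uv_base} (linear coupling).
#' @param mean_vv Per-lambda \eqn{\langle H_{vv} \rangle}.
#' @param entropy Optional per-lambda exact entropy.
#' @param stderr_uv_base,stderr_uv,stderr_vv Optional standard errors.
#' @return Object of class \code{thermo_curve} (a data frame).
#' @export
thermo_curve <- function(lambda, mean_uv_base, mean_uv = lambda * mean_uv_base,
                         mean_vv, entropy = NULL, stderr_uv_base = NULL,
                         stderr_uv = NULL, stderr_vv = NULL) {
  validate_lambda_grid(lambda)
  n <- length(lambda)
  stopifnot(length(mean_uv_base) == n, length(mean_uv) == n,
            length(mean_vv) == n)
  df <- data.frame(lambda = lambda, mean_uv_base = mean_uv_base,
                   mean_uv = mean_uv, mean_vv = mean_vv)
  if (!is.null(entropy)) df$entropy <- entropy
  if (!is.null(stderr_uv_base)) df$stderr_uv_base <- stderr_uv_base
  if (!is.null(stderr_uv)) df$stderr_uv <- stderr_uv
  if (!is.null(stderr_vv)) df$stderr_vv <- stderr_vv
  class(df) <- c("thermo_curve", "data.frame")
  df
}

#' Free energy difference by thermodynamic integration
#'
#' \eqn{\Delta F = \int_0^1 \langle \partial H/\partial \lambda \rangle\,
#' d\lambda} by the trapezoidal rule on the curve's grid.
#'
#' @param curve A \code{thermo_curve}.
#' @return The free energy difference between lambda = 1 and lambda = 0.
#' @export
ti_free_energy <- function(curve) {
  if (is.null(curve$mean_uv_base)) stop("curve lacks the TI integrand")
  pracma::trapz(curve$lambda, curve$mean_uv_base)
}

#' Canonical (Ben-Naim / Yu-Karplus) decomposition of the solvation free energy
#'
#' Splits \eqn{\Delta F = \Delta U - T\Delta S} into solute-solvent and
#' solvent-solvent parts: \eqn{\Delta U_{uv} = \langle H_{uv}\rangle_{\lambda=1}},
#' \eqn{\Delta U_{vv} = \langle H_{vv}\rangle_1 - \langle H_{vv}\rangle_0},
#' \eqn{T\Delta S_{uv} = \Delta U_{uv} - \Delta F} and
#' \eqn{T\Delta S_{vv} = \Delta U_{vv}}.  The last identity is the Ben-Naim
#' theorem: the solvent-solvent ("solvent reorganization") energy and entropy
#' terms cancel exactly in \eqn{\Delta F}, which therefore equals
#' \eqn{\Delta U_{uv} - T\Delta S_{uv}}.
#'
#' When the curve carries standard errors they are propagated in quadrature
#' assuming independent windows (trapezoid weights for \eqn{\Delta F}).
#'
#' @param curve A \code{thermo_curve} spanning [0, 1].
#' @param beta Inverse temperature (used only for bookkeeping; the curve's
#'   averages are already canonical at this beta).
#' @return Object of class \code{decomposition_result}: a list with
#'   \code{dU_uv}, \code{dU_vv}, \code{TdS_uv}, \code{TdS_vv}, \code{dF},
#'   \code{dU}, \code{TdS}, and \code{stderr} (named vector, possibly NA).
#' @export
canonical_decompose <- function(curve, beta = 1) {
  validate_lambda_grid(curve$lambda)
  n <- nrow(curve)
  dF <- ti_free_energy(curve)
  dU_uv <- curve$mean_uv[n]
  dU_vv <- curve$mean_vv[n] - curve$mean_vv[1]
  TdS_uv <- dU_uv - dF
  TdS_vv <- dU_vv
  dU <- dU_uv + dU_vv
  TdS <- TdS_uv + TdS_vv
  se <- c(dU_uv = NA_real_, dU_vv = NA_real_, dF = NA_real_,
          TdS_uv = NA_real_, TdS_vv = NA_real_)
  if (!is.null(curve$stderr_uv_base)) {
    h <- diff(curve$lambda)
    w <- c(h / 2, 0) + c(0, h / 2)          # trapezoid weights
    se["dF"] <- sqrt(sum((w * curve$stderr_uv_base)^2))
    if (!is.null(curve$stderr_uv)) {
      se["dU_uv"] <- curve$stderr_uv[n]
      se["TdS_uv"] <- sqrt(se["dU_uv"]^2 + se["dF"]^2)
    }
    if (!is.null(curve$stderr_vv)) {
      se["dU_vv"] <- sqrt(curve$stderr_vv[n]^2 + curve$stderr_vv[1]^2)
      se["TdS_vv"] <- se["dU_vv"]
    }
  }
  structure(list(dU_uv = dU_uv, dU_vv = dU_vv, TdS_uv = TdS_uv,
                 TdS_vv = TdS_vv, dF = dF, dU = dU, TdS = TdS,
                 beta = beta, stderr = se),
            class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat("Canonical solvation free-energy decomposition\n")
  cat(sprintf("  dF     = %9.4f\n", x$dF))
  cat(sprintf("  dU     = %9.4f  (uv %9.4f, vv %9.4f)\n", x$dU, x$dU_uv, x$dU_vv))
  cat(sprintf("  TdS    = %9.4f  (uv %9.4f, vv %9.4f)\n", x$TdS, x$TdS_uv, x$TdS_vv))
  cat(sprintf("  Ben-Naim residual dU_vv - TdS_vv = %.2e\n", x$dU_vv - x$TdS_vv))
  invisible(x)
}

#' Exact thermo curve of the Ising model by enumeration
#'
#' @param spec A \code{lattice_spec}.
#' @param lambda_values Coupling grid spanning [0, 1].
#' @return A \code{thermo_curve} including the exact per-lambda entropy.
#' @export
ising_thermo_curve <- function(spec, lambda_values = lambda_grid(251)) {
  validate_lambda_grid(lambda_values)
  tb <- ising_lambda_tables(spec, list())
  st <- lapply(lambda_values, function(l) ising_cell_stats(tb, spec, l))
  base <- vapply(st, `[[`, 0, "mean_uv_base")
  thermo_curve(lambda = lambda_values,
               mean_uv_base = base,
               mean_uv = lambda_values * base,
               mean_vv = vapply(st, `[[`, 0, "mean_vv"),
               entropy = vapply(st, `[[`, 0, "S"))
}

#' Exact entropy difference of an enumerable system across the coupling path
#'
#' @param spec A \code{lattice_spec} (must be exactly enumerable).
#' @param lambda_values Coupling grid spanning [0, 1].
#' @return List with the per-lambda \code{entropy} curve and
#'   \code{dS = S(1) - S(0)} (so \code{-dS} is the entropic free-energy
#'   change \eqn{-T\Delta S_{TI}} at \eqn{T = 1}).
#' @export
entropy_difference_exact <- function(spec, lambda_values = lambda_grid(251)) {
  if (spec$side_length^2 > 20L) stop("system is not exactly enumerable")
  curve <- ising_thermo_curve(spec, lambda_values)
  list(lambda = curve$lambda, entropy = curve$entropy,
       dS = curve$entropy[nrow(curve)] - curve$entropy[1])
}

#' Free energy from direct partition-function enumeration
#'
#' Independent check of \code{\link{ti_free_energy}}:
#' \eqn{\Delta F = -(1/\beta)\ln(Z_1/Z_0)} by summing Boltzmann weights.
#'
#' @param spec A \code{lattice_spec}.
#' @return The exact free energy difference.
#' @export
free_energy_enumeration <- function(spec) {
  hvv <- energy_vv_all(spec)
  f <- shell_field_all(spec)
  lw0 <- -spec$beta * hvv
  lw1 <- -spec$beta * (hvv - spec$field_max * f)
  m <- max(c(lw0, lw1))
  -(1 / spec$beta) * (log(sum(exp(lw1 - m))) - log(sum(exp(lw0 - m))))
}
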
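# Reduced-scale Lennard-Jones "argon-type" fluid with an optional immobilized
# solute, sampled by single-particle-move Metropolis Monte Carlo under NVT.
# Configurational averages are identical to those of thermostatted MD; MC
# avoids integrator and thermostat parameters.  Energies kJ/mol, lengths nm.

#' Lennard-Jones pair parameters with a switched cutoff
#'
#' The potential \eqn{4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6]} is taken
#' smoothly to zero between \code{switch_start} and \code{cutoff} by the C2
#' smooth-step \eqn{S(x) = 1 - 10x^3 + 15x^4 - 6x^5},
#' \eqn{x = (r - r_1)/(r_c - r_1)}, applied to the potential.
#'
#' @param sigma Particle size sigma in nm (default 0.3405, argon).
#' @param epsilon Well depth in kJ/mol (default 0.996, argon).
#' @param switch_start Switch onset r1 in nm (default 1.0).
#' @param cutoff Cutoff rc in nm (default 1.2).
#' @return Object of class \code{lj_params}.
#' @export
lj_params <- function(sigma = 0.3405, epsilon = 0.996, switch_start = 1.0,
                      cutoff = 1.2) {
  if (!(sigma > 0 && sigma < switch_start && switch_start < cutoff))
    stop("need 0 < sigma < switch_start < cutoff")
  structure(list(sigma = sigma, epsilon = epsilon,
                 switch_start = switch_start, cutoff = cutoff),
            class = "lj_params")
}

lj_par_vec <- function(p) c(p$sigma, p$epsilon, p$switch_start, p$cutoff)

#' Switched Lennard-Jones pair potential
#'
#' @param r Distance(s) in nm, > 0.
#' @param params An \code{lj_params}.
#' @return Energy in kJ/mol; exactly 0 for \code{r >= cutoff}, unmodified LJ
#'   for \code{r <= switch_start}, continuously differentiable throughout.
#' @export
pair_potential <- function(r, params) {
  if (any(r <= 0)) stop("r must be positive")
  vapply(r, lj_pair_cpp, 0, par = lj_par_vec(params))
}

# Lorentz-Berthelot combination for solute-solvent interactions
combine_lb <- function(a, b) {
  lj_params(sigma = (a$sigma + b$sigma) / 2,
            epsilon = sqrt(a$epsilon * b$epsilon),
            switch_start = a$switch_start, cutoff = a$cutoff)
}

#' Particle-system specification
#'
#' Describes N solvent particles in a periodic cubic box at fixed
#' temperature, optionally with one immobilized solute at the box centre
#' whose solute-solvent interaction (Lorentz-Berthelot cross parameters) is
#' scaled by the coupling parameter \code{lambda}.
#'
#' @param n_solvent Number of solvent particles.
#' @param box_length Cubic box edge in nm (> 2 * cutoff).
#' @param temperature Temperature in K (default 120).
#' @param solvent_params Solvent \code{lj_params}.
#' @param solute_params Solute \code{lj_params} or NULL for no solute.  The
#'   default doubles both sigma and epsilon of the solvent.
#' @param lambda Coupling parameter in [0, 1].
#' @param softcore Use the Beutler soft-core coupling path (default TRUE);
#'   FALSE gives plain linear scaling.
#' @param softcore_alpha Soft-core alpha (default 0.5).
#' @return Object of class \code{system_spec}.
#' @export
system_spec <- function(n_solvent, box_length, temperature = 120,
                        solvent_params = lj_params(),
                        solute_params = lj_params(
                          sigma = 2 * solvent_params$sigma,
                          epsilon = 2 * solvent_params$epsilon,
                          switch_start = solvent_params$switch_start,
                          cutoff = solvent_params$cutoff),
                        lambda = 1, softcore = TRUE, softcore_alpha = 0.5) {
  if (box_length <= 2 * solvent_params$cutoff)
    stop("box_length must exceed twice the cutoff")
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  structure(list(n_solvent = as.integer(n_solvent), box_length = box_length,
                 temperature = temperature, solvent_params = solvent_params,
                 solute_params = solute_params,
                 solute_position = rep(box_length / 2, 3),
                 lambda = lambda, softcore = softcore,
                 softcore_alpha = softcore_alpha),
            class = "system_spec")
}

#' Reduced-scale argon system at the reference liquid density
#'
#' Convenience constructor: N argon-type particles at the density of 512
#' particles in a (3.073 nm)^3 box (17.64 nm^-3), with the switch window
#' shortened so the periodic box of the reduced system still exceeds twice
#' the cutoff.
#'
#' @param n_solvent Number of solvent particles (default 64).
#' @param lambda Coupling parameter (default 1; 0 decouples the solute).
#' @param solute Include the immobilized solute (default TRUE).
#' @param ... Passed on to \code{\link{system_spec}}.
#' @return A \code{system_spec}.
#' @export
reduced_argon_spec <- function(n_solvent = 64, lambda = 1, solute = TRUE, ...) {
  density <- 512 / 3.073^3
  box <- (n_solvent / density)^(1 / 3)
  rc <- min(1.2, 0.48 * box)
  r1 <- rc - 0.15
  sv <- lj_params(switch_start = r1, cutoff = rc)
  # the solute's own switch window only has to satisfy its size invariant;
  # solute-solvent interactions use the solvent window via Lorentz-Berthelot
  su <- if (solute) lj_params(sigma = 2 * sv$sigma, epsilon = 2 * sv$epsilon,
                              switch_start = max(r1, 2.1 * sv$sigma),
                              cutoff = max(rc, 2.1 * sv$sigma + 0.15))
        else NULL
  system_spec(n_solvent = n_solvent, box_length = box,
              solvent_params = sv, solute_params = su, lambda = lambda, ...)
}

#' Monte Carlo run configuration
#'
#' @param n_steps Production single-particle moves.
#' @param equilibration_steps Discarded equilibration moves (the maximum
#'   displacement is auto-tuned toward 30-60 percent acceptance during
#'   equilibration only).
#' @param output_stride Store one frame every this many production moves.
#' @param max_displacement Initial maximum displacement in nm.
#' @param seed Integer RNG seed.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(n_steps = 200000L, equilibration_steps = 50000L,
                       output_stride = 50L, max_displacement = 0.05,
                       seed = 1L) {
  stopifnot(n_steps > 0, equilibration_steps >= 0, output_stride > 0,
            max_displacement > 0)
  structure(list(n_steps = as.integer(n_steps),
                 equilibration_steps = as.integer(equilibration_steps),
                 output_stride = as.integer(output_stride),
                 max_displacement = max_displacement,
                 seed = as.integer(seed)),
            class = "sim_config")
}

beta_of <- function(spec) 1 / (0.008314462618 * spec$temperature)

uv_cross_params <- function(spec) {
  if (is.null(spec$solute_params)) return(NULL)
  combine_lb(spec$solvent_params, spec$solute_params)
}

#' Solvent-solvent and solute-solvent energies of one configuration
#'
#' Minimum-image pair sums with the switched potential; the solute-solvent
#' part follows the spec's coupling path (\code{U_uv} is the lambda-scaled
#' energy, \code{dU_dlambda} its analytic lambda-derivative).
#'
#' @param positions N x 3 solvent coordinates (nm), wrapped or wrappable.
#' @param spec A \code{system_spec}.
#' @return List with \code{U_vv}, \code{U_uv} and \code{dU_dlambda} (kJ/mol).
#' @export
total_energies <- function(positions, spec) {
  positions <- as.matrix(positions)
  uv <- uv_cross_params(spec)
  total_energies_cpp(positions, spec$box_length,
                     lj_par_vec(spec$solvent_params),
                     if (is.null(uv)) numeric(4) else lj_par_vec(uv),
                     if (is.null(uv)) numeric(0) else spec$solute_position,
                     spec$lambda, spec$softcore, spec$softcore_alpha)
}

# simple-cubic initial placement avoiding the solute; soft-push relaxation
# if any pair comes closer than 0.85 sigma
initial_positions <- function(spec) {
  n <- spec$n_solvent
  L <- spec$box_length
  m <- ceiling(n^(1 / 3))
  g <- (seq_len(m) - 0.5) * L / m
  grid <- as.matrix(expand.grid(x = g, y = g, z = g))
  if (!is.null(spec$solute_params)) {
    d2 <- colSums((t(grid) - spec$solute_position)^2)
    grid <- grid[order(-d2), , drop = FALSE]   # fill from far side first
  }
  pos <- grid[seq_len(n), , drop = FALSE]
  dimnames(pos) <- NULL
  soft_push(pos, spec)
}

soft_push <- function(pos, spec, min_frac = 0.85, max_iter = 200) {
  L <- spec$box_length
  smin <- min_frac * spec$solvent_params$sigma
  for (it in seq_len(max_iter)) {
    moved <- FALSE
    for (i in seq_len(nrow(pos) - 1)) {
      d <- sweep(pos[(i + 1):nrow(pos), , drop = FALSE], 2, pos[i, ])
      d <- d - L * round(d / L)
      r <- sqrt(rowSums(d^2))
      bad <- which(r < smin)
      for (b in bad) {
        j <- i + b
        push <- if (r[b] > 1e-12) d[b, ] / r[b] else c(1, 0, 0)
        pos[j, ] <- (pos[j, ] + push * (smin - r[b]) / 2) %% L
        pos[i, ] <- (pos[i, ] - push * (smin - r[b]) / 2) %% L
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  if (moved) message("soft-push relaxation reached its iteration cap")
  pos
}

#' Metropolis Monte Carlo sampling of the particle system
#'
#' Single-particle displacement moves with Metropolis acceptance
#' \eqn{\min(1, e^{-\beta \Delta U})}; the solute never moves.  Incremental
#' energy bookkeeping is checked against full recomputation at every stored
#' frame (maximum deviation reported).
#'
#' @param spec A \code{system_spec}.
#' @param config A \code{sim_config}.
#' @param positions Optional N x 3 starting coordinates; default lattice
#'   placement with soft-push relaxation of overlaps.
#' @param store_frames Keep coordinates (default TRUE); FALSE stores only the
#'   energy series.
#' @return List with \code{trajectory} (or NULL), \code{energies} (data frame
#'   \code{frame}, \code{U_vv}, \code{U_uv}, \code{dU_dlambda}),
#'   \code{acceptance}, \code{max_displacement}, \code{bookkeeping_error} and
#'   \code{final_positions}.
#' @export
mc_run <- function(spec, config = sim_config(), positions = NULL,
                   store_frames = TRUE) {
  if (is.null(positions)) positions <- initial_positions(spec)
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) == spec$n_solvent)
  uv <- uv_cross_params(spec)
  res <- mc_run_cpp(positions, spec$box_length,
                    lj_par_vec(spec$solvent_params),
                    if (is.null(uv)) numeric(4) else lj_par_vec(uv),
                    if (is.null(uv)) numeric(0) else spec$solute_position,
                    spec$lambda, spec$softcore, spec$softcore_alpha,
                    beta_of(spec), config$n_steps,
                    config$equilibration_steps, config$output_stride,
                    config$max_displacement, config$seed, store_frames)
  nf <- res$n_frames
  traj <- NULL
  if (store_frames) {
    coords <- array(res$frames, dim = c(nf, spec$n_solvent, 3))
    traj <- trajectory(coords, spec$box_length)
  }
  list(trajectory = traj,
       energies = data.frame(frame = seq_len(nf), U_vv = res$U_vv[seq_len(nf)],
                             U_uv = res$U_uv[seq_len(nf)],
                             dU_dlambda = res$dU_dlambda[seq_len(nf)]),
       acceptance = res$acceptance, max_displacement = res$max_disp,
       bookkeeping_error = res$bookkeeping_error,
       final_positions = res$final_positions)
}

window_stats <- function(x) {
  n <- length(x)
  c(mean = mean(x), se = stats::sd(x) / sqrt(n))
}

#' Thermodynamic integration over lambda windows of the particle system
#'
#' Runs one Monte Carlo simulation per lambda window (seeded independently
#' from \code{config$seed}), carrying the final configuration of each window
#' into the next as its starting point, and collects per-window averages of
#' the TI integrand and the interaction energies with standard errors (frames
#' treated as independent).  A first-half/second-half drift test flags
#' windows whose integrand mean moved by more than 3 combined standard
#' errors.
#'
#' @param spec A \code{system_spec} (its lambda is overridden per window).
#' @param lambda_values Equidistant grid spanning [0, 1] (default 21 windows
#'   at reduced scale).
#' @param config A \code{sim_config} describing each window's run.
#' @return A \code{thermo_curve} with standard errors; attribute
#'   \code{"drift_flagged"} lists flagged window indices.
#' @export
ti_particles <- function(spec, lambda_values = lambda_grid(21),
                         config = sim_config()) {
  validate_lambda_grid(lambda_values)
  pos <- initial_positions(spec)
  rows <- vector("list", length(lambda_values))
  flagged <- integer()
  for (i in seq_along(lambda_values)) {
    w <- spec
    w$lambda <- lambda_values[i]
    cfg <- config
    cfg$seed <- config$seed + i * 1000L
    run <- mc_run(w, cfg, positions = pos, store_frames = FALSE)
    pos <- run$final_positions
    e <- run$energies
    half <- seq_len(nrow(e) %/% 2)
    m1 <- window_stats(e$dU_dlambda[half])
    m2 <- window_stats(e$dU_dlambda[-half])
    if (abs(m1["mean"] - m2["mean"]) >
        3 * sqrt(m1["se"]^2 + m2["se"]^2) + 1e-12)
      flagged <- c(flagged, i)
    rows[[i]] <- c(window_stats(e$dU_dlambda), window_stats(e$U_uv),
                   window_stats(e$U_vv))
  }
  m <- do.call(rbind, rows)
  curve <- thermo_curve(lambda = lambda_values, mean_uv_base = m[, 1],
                        mean_uv = m[, 3], mean_vv = m[, 5],
                        stderr_uv_base = m[, 2], stderr_uv = m[, 4],
                        stderr_vv = m[, 6])
  attr(curve, "drift_flagged") <- flagged
  curve
}

#' Free energy by exponential (free-energy-perturbation) averaging
#'
#' Independent estimator used to cross-check \code{\link{ti_free_energy}}:
#' for each window samples at \eqn{\lambda_i} and accumulates
#' \eqn{-\beta^{-1} \ln \langle e^{-\beta[U(\lambda_{i+1}) -
#' U(\lambda_i)]} \rangle_{\lambda_i}}.
#'
#' @param spec A \code{system_spec}.
#' @param lambda_values Grid spanning [0, 1].
#' @param config A \code{sim_config} per window.
#' @return List with \code{dF}, its standard error \code{stderr} (delta
#'   method per window, combined in quadrature) and per-step
#'   \code{increments}.
#' @export
fep_free_energy <- function(spec, lambda_values = lambda_grid(21),
                            config = sim_config()) {
  validate_lambda_grid(lambda_values)
  beta <- beta_of(spec)
  pos <- initial_positions(spec)
  inc <- numeric(length(lambda_values) - 1)
  se <- numeric(length(lambda_values) - 1)
  for (i in seq_len(length(lambda_values) - 1)) {
    w <- spec
    w$lambda <- lambda_values[i]
    cfg <- config
    cfg$seed <- config$seed + i * 1000L
    run <- mc_run(w, cfg, positions = pos, store_frames = TRUE)
    pos <- run$final_positions
    wnext <- spec
    wnext$lambda <- lambda_values[i + 1]
    du <- vapply(seq_len(n_frames(run$trajectory)), function(f) {
      p <- get_frame(run$trajectory, f)
      total_energies(p, wnext)$U_uv - run$energies$U_uv[f]
    }, 0)
    w <- exp(-beta * du)
    inc[i] <- -log(mean(w)) / beta
    se[i] <- stats::sd(w) / (mean(w) * sqrt(length(w))) / beta
  }
  list(dF = sum(inc), stderr = sqrt(sum(se^2)), increments = inc)
}
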
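# Permutation reduction: relabel identical particles frame by frame so that
# each label's positional distribution is compact.  Labels are assigned by
# minimising the summed minimum-image squared displacement to a reference
# frame (optimal linear assignment); all permutation-invariant observables
# are unchanged.

#' Assignment cost matrix between a frame and a reference
#'
#' \code{cost[i, j]} is the minimum-image squared distance between particle
#' \code{i} of the frame and reference slot \code{j}.
#'
#' @param frame,ref N x 3 coordinate matrices (nm).
#' @param box Periodic box edge lengths (length 3 or recycled).
#' @param species Optional per-particle labels; must be identical between
#'   frame and reference (particles may only be permuted within a species).
#' @param ref_species Labels of the reference slots (default \code{species}).
#' @return N x N numeric cost matrix (nm^2).
#' @export
assignment_cost <- function(frame, ref, box, species = NULL,
                            ref_species = species) {
  frame <- as.matrix(frame); ref <- as.matrix(ref)
  if (!identical(dim(frame), dim(ref)))
    stop("frame and reference must have the same particle count")
  if (!is.null(species) && !identical(sort(species), sort(ref_species)))
    stop("species mismatch between frame and reference")
  box <- rep(as.numeric(box), length.out = 3)
  cost <- assignment_cost_cpp(frame, ref, box)
  if (!is.null(species)) {
    # forbid cross-species assignments
    cost[outer(species, ref_species, "!=")] <- Inf
  }
  cost
}

#' Solve a linear assignment problem
#'
#' Minimum-cost perfect matching of rows to columns (shortest augmenting
#' path, exact).
#'
#' @param cost Square numeric cost matrix.
#' @return Integer vector \code{a} with \code{a[i]} the column assigned to
#'   row \code{i}.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  # replace Inf by a large finite penalty so the solver stays numeric
  if (any(!is.finite(cost))) {
    big <- 1e6 * (1 + max(cost[is.finite(cost)], 0))
    cost[!is.finite(cost)] <- big
  }
  solve_assignment_cpp(cost)
}

#' Permutation-reduce a trajectory against a reference frame
#'
#' Per frame, particle labels are permuted to minimise the total
#' minimum-image squared displacement to the reference.  The multiset of
#' coordinates in every frame is unchanged; only labels move.
#'
#' @param traj A \code{trajectory}.
#' @param ref N x 3 reference coordinates (e.g. \code{get_frame(traj, i)}).
#' @return The relabeled \code{trajectory}, with attribute
#'   \code{"reduced" = TRUE}.
#' @export
permutation_reduce <- function(traj, ref) {
  ref <- as.matrix(ref)
  n <- n_particles(traj)
  if (nrow(ref) != n) stop("reference particle count differs from trajectory")
  out <- traj$coords
  for (f in seq_len(n_frames(traj))) {
    pos <- get_frame(traj, f)
    a <- solve_assignment(assignment_cost(pos, ref, traj$box, traj$species,
                                          traj$species))
    out[f, a, ] <- pos
  }
  res <- trajectory(out, traj$box, traj$species)
  attr(res, "reduced") <- TRUE
  res
}

#' Randomly select reference frames for permutation reduction
#'
#' @param traj A \code{trajectory}.
#' @param n_refs Number of distinct reference frames (default 50).
#' @param seed Integer seed making the selection reproducible.
#' @return Object of class \code{reference_set}: list of reference frames,
#'   their frame indices and the seed.
#' @export
select_references <- function(traj, n_refs = 50, seed = 1L) {
  n_refs <- as.integer(n_refs)
  if (n_refs > n_frames(traj)) stop("n_refs exceeds the number of frames")
  if (n_refs < 1) stop("need at least one reference")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  idx <- sort(sample.int(n_frames(traj), n_refs))
  structure(list(references = lapply(idx, function(i) get_frame(traj, i)),
                 indices = idx, seed = as.integer(seed)),
            class = "reference_set")
}

#' Estimate a trajectory functional over a set of references
#'
#' Permutation-reduces the trajectory against each reference, applies the
#' estimator, and reports the mean and the standard error over references.
#'
#' @param traj A \code{trajectory}.
#' @param refs A \code{reference_set}.
#' @param estimator Function mapping a (reduced) \code{trajectory} to a
#'   numeric value (or a named numeric vector of values, estimated jointly).
#' @return List with \code{value}, \code{stderr} (both matching the
#'   estimator's shape), \code{per_reference} values and \code{n_refs}.
#' @export
estimate_with_references <- function(traj, refs, estimator) {
  stopifnot(inherits(refs, "reference_set"))
  vals <- lapply(refs$references, function(r)
    estimator(permutation_reduce(traj, r)))
  m <- do.call(rbind, vals)
  if (nrow(m) == 1) {
    warning("single reference: standard error undefined, reported as 0")
    se <- rep(0, ncol(m))
  } else {
    se <- apply(m, 2, stats::sd) / sqrt(nrow(m))
  }
  value <- colMeans(m)
  names(se) <- colnames(m)
  if (ncol(m) == 1 && is.null(colnames(m))) {
    value <- unname(value)
    se <- unname(se)
  }
  list(value = value, stderr = se, per_reference = m, n_refs = nrow(m))
}
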
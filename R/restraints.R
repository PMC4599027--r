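# Flat-bottom distance restraints --------------------------------------------

#' Flat-bottom distance restraint specification
#'
#' The restraint is anchored at an initial distance `r_i` (nm) and defines
#' `r_0 = r_i - 0.30`, `r_1 = r_i + 0.30`, `r_2 = r_1 + 1` (all nm): zero
#' penalty on the flat bottom `[r_0, r_1]`, quadratic outside it, switching
#' to linear beyond `r_2`.
#'
#' @param r_init_nm Initial (anchor) distance in nm; must satisfy
#'   `r_init_nm >= 0.30` so that `r_0 >= 0`.
#' @param k Force constant (energy / nm^2; arbitrary units, default 1000).
#' @param half_width_nm Half-width of the flat bottom (default 0.30 nm).
#' @param linear_offset_nm Distance beyond `r_1` at which the penalty turns
#'   linear (default 1 nm).
#' @return An object of class `restraint_spec` with fields `r_init_nm`,
#'   `r0_nm`, `r1_nm`, `r2_nm`, `k`.
#' @export
restraint_spec <- function(r_init_nm, k = 1000, half_width_nm = 0.30,
                           linear_offset_nm = 1) {
  stopifnot(r_init_nm >= 0, k > 0, half_width_nm > 0, linear_offset_nm > 0)
  r0 <- r_init_nm - half_width_nm
  if (r0 < 0) stop("r_0 = r_init - ", half_width_nm,
                   " nm is negative; increase r_init_nm")
  structure(list(r_init_nm = r_init_nm, r0_nm = r0,
                 r1_nm = r_init_nm + half_width_nm,
                 r2_nm = r_init_nm + half_width_nm + linear_offset_nm,
                 k = k), class = "restraint_spec")
}

#' @export
print.restraint_spec <- function(x, ...) {
  cat(sprintf(paste0("Flat-bottom restraint: r0 = %.3f, r1 = %.3f, ",
                     "r2 = %.3f nm (k = %g)\n"),
              x$r0_nm, x$r1_nm, x$r2_nm, x$k))
  invisible(x)
}

#' Flat-bottom restraint energy
#'
#' Piecewise potential: `(k/2)(r_0 - r)^2` below `r_0`; 0 on `[r_0, r_1]`;
#' `(k/2)(r - r_1)^2` on `(r_1, r_2]`; linear above `r_2` with slope
#' `k (r_2 - r_1)` and matching value at `r_2`. Continuous and once
#' differentiable everywhere.
#'
#' @param r_nm Distance(s) in nm (vectorised).
#' @param spec A [restraint_spec()].
#' @return Energy value(s) in the spec's units.
#' @export
restraint_energy <- function(r_nm, spec) {
  stopifnot(inherits(spec, "restraint_spec"))
  r <- as.numeric(r_nm)
  if (any(r < 0)) stop("distances must be non-negative")
  k <- spec$k; r0 <- spec$r0_nm; r1 <- spec$r1_nm; r2 <- spec$r2_nm
  e <- numeric(length(r))
  below <- r < r0
  quad <- r > r1 & r <= r2
  lin <- r > r2
  e[below] <- 0.5 * k * (r0 - r[below])^2
  e[quad] <- 0.5 * k * (r[quad] - r1)^2
  e[lin] <- 0.5 * k * (r2 - r1)^2 + k * (r2 - r1) * (r[lin] - r2)
  e
}

#' Restraint usage (violation) fraction over a trajectory
#'
#' Percentage of frames in which the atom-atom distance falls outside the
#' flat bottom `[r_0, r_1]`, i.e. frames where the restraint does work.
#' Trajectory coordinates are in Angstrom and converted to nm for the
#' comparison.
#'
#' @param traj A `trajectory`.
#' @param atomA,atomB Atom index or filter list resolving to exactly one
#'   atom each.
#' @param spec A [restraint_spec()].
#' @return Percentage in `[0, 100]`, with attribute `"series"` (logical
#'   per-frame violation).
#' @export
restraint_violation_fraction <- function(traj, atomA, atomB, spec) {
  stopifnot(inherits(traj, "trajectory"), inherits(spec, "restraint_spec"))
  d_nm <- distance_stats(traj, atomA, atomB)$series / 10
  violated <- d_nm < spec$r0_nm | d_nm > spec$r1_nm
  structure(100 * mean(violated), series = violated)
}
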
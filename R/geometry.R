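# Superposition, RMSD/RMSF, hydrogen bonds, ring stacking --------------------

#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation (determinant +1) and translation minimising the
#' RMSD between `mobile` and `reference` point sets, via SVD of the
#' cross-covariance matrix with reflection correction.
#'
#' @param mobile,reference n x 3 coordinate matrices (n >= 3,
#'   non-collinear), row-matched.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3)
#'   and `rmsd` (Angstrom). The fitted coordinates are
#'   `mobile %*% t(rotation) + translation` (rows).
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (ncol(mobile) != 3L || ncol(reference) != 3L)
    stop("coordinate matrices must have 3 columns")
  if (nrow(mobile) != nrow(reference))
    stop("point counts differ")
  if (nrow(mobile) < 3L) stop("need at least 3 points")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)
  sv <- svd(H)
  # collinear (or coincident) point sets leave the rotation underdetermined
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
    stop("degenerate (collinear) point set; superposition undefined")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = as.numeric(cr - R %*% cm), rmsd = rmsd)
}

# apply a kabsch_superpose result to coordinates
apply_transform <- function(coords, fit) {
  sweep(as.matrix(coords) %*% t(fit$rotation), 2, -fit$translation)
}

#' Per-frame RMSD of a trajectory
#'
#' Each frame's selection is rigid-body superposed onto the reference
#' frame's selection before the deviation is measured.
#'
#' @param traj A `trajectory`.
#' @param reference Reference frame index (default 1).
#' @param selection Atom indices or a filter list for [select_atoms()];
#'   default all alpha-carbons (`atom = "CA"`).
#' @return Numeric vector of per-frame RMSD values (Angstrom).
#' @export
rmsd_series <- function(traj, reference = 1L, selection = list(atom = "CA")) {
  stopifnot(inherits(traj, "trajectory"))
  sel <- .resolve_selection(traj, selection, what = "selection")
  ref <- traj$frames[[reference]][sel, , drop = FALSE]
  vapply(traj$frames, function(fr) {
    kabsch_superpose(fr[sel, , drop = FALSE], ref)$rmsd
  }, numeric(1))
}

#' Per-atom root-mean-square fluctuation
#'
#' Frames are superposed onto the mean structure (two refinement passes:
#' fit to the first frame, re-fit to the resulting mean, then once more),
#' after which each selected atom's RMS deviation from its mean position is
#' reported.
#'
#' @inheritParams rmsd_series
#' @return Data frame with `index`, `resno`, `atom`, `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, selection = list(atom = "CA")) {
  stopifnot(inherits(traj, "trajectory"))
  if (traj$n_frames < 2L) stop("RMSF needs at least 2 frames")
  sel <- .resolve_selection(traj, selection, what = "selection")
  coords <- lapply(traj$frames, function(fr) fr[sel, , drop = FALSE])
  ref <- coords[[1L]]
  for (pass in 1:2) {
    fitted <- lapply(coords, function(x) {
      f <- kabsch_superpose(x, ref)
      apply_transform(x, f)
    })
    ref <- Reduce(`+`, fitted) / length(fitted)
  }
  mean_xyz <- ref
  sq <- vapply(fitted, function(x) rowSums((x - mean_xyz)^2),
               numeric(nrow(mean_xyz)))
  sq <- matrix(sq, nrow = nrow(mean_xyz))
  at <- traj$topology$atoms[sel, , drop = FALSE]
  data.frame(index = sel, resno = at$resno, atom = at$atom,
             rmsf = sqrt(rowMeans(sq)), row.names = NULL)
}

# Hydrogen bonds --------------------------------------------------------------

#' Hydrogen-bond detection criteria
#'
#' @param distance_cutoff Maximum donor-acceptor heavy-atom distance in
#'   Angstrom (default 3.0).
#' @param angle_cutoff Maximum deviation from linearity of the
#'   donor-H...acceptor angle, in degrees (default 30).
#' @return An object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(distance_cutoff = 3.0, angle_cutoff = 30) {
  stopifnot(distance_cutoff > 0, angle_cutoff > 0)
  structure(list(distance_cutoff = distance_cutoff,
                 angle_cutoff = angle_cutoff), class = "hbond_criteria")
}

.dist3 <- function(a, b) sqrt(sum((a - b)^2))

# deviation from linearity (degrees) of D-H...A measured at the hydrogen
.hbond_angle_dev <- function(d, h, a) {
  v1 <- d - h; v2 <- a - h
  cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
  180 - acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Detect hydrogen bonds in a single frame
#'
#' Donors and acceptors are N and O heavy atoms. Each hydrogen is assigned
#' to the nearest N/O within 1.2 Angstrom (its donor); a bond D-H...A is
#' reported iff the D-A heavy-atom distance is within `distance_cutoff` and
#' the deviation of D-H...A from linearity is within `angle_cutoff`.
#'
#' @param structure A `structure`.
#' @param coords Optional n x 3 matrix overriding the structure's
#'   coordinates (e.g. one trajectory frame).
#' @param criteria An [hbond_criteria()].
#' @return Data frame with atom indices `donor`, `hydrogen`, `acceptor`,
#'   plus `distance` and `angle_dev`. Empty (with a warning) when the
#'   structure has no hydrogens.
#' @export
detect_hbonds <- function(structure, coords = NULL,
                          criteria = hbond_criteria()) {
  stopifnot(inherits(structure, "structure"),
            inherits(criteria, "hbond_criteria"))
  xyz <- if (is.null(coords)) structure$coords else as.matrix(coords)
  el <- structure$atoms$element
  hyd <- which(el == "H")
  heavy <- which(el %in% c("N", "O"))
  empty <- data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), distance = numeric(0),
                      angle_dev = numeric(0))
  if (length(hyd) == 0L) {
    warning("no hydrogens in structure; cannot detect hydrogen bonds")
    return(empty)
  }
  if (length(heavy) == 0L) return(empty)
  out <- list()
  for (h in hyd) {
    dd <- vapply(heavy, function(i) .dist3(xyz[h, ], xyz[i, ]), numeric(1))
    if (min(dd) > 1.2) next  # free hydrogen, no covalent donor
    don <- heavy[which.min(dd)]
    for (acc in heavy) {
      if (acc == don) next
      dist_da <- .dist3(xyz[don, ], xyz[acc, ])
      if (dist_da > criteria$distance_cutoff) next
      dev <- .hbond_angle_dev(xyz[don, ], xyz[h, ], xyz[acc, ])
      if (dev > criteria$angle_cutoff) next
      out[[length(out) + 1L]] <- data.frame(
        donor = don, hydrogen = h, acceptor = acc,
        distance = dist_da, angle_dev = dev)
    }
  }
  if (length(out) == 0L) return(empty)
  do.call(rbind, out)
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' Percentage of frames in which the given donor-acceptor pair satisfies
#' the hydrogen-bond criteria (per-frame existence, no smoothing).
#'
#' @param traj A `trajectory`.
#' @param donor,acceptor Each an atom index or a filter list for
#'   [select_atoms()] resolving to exactly one heavy atom.
#' @param criteria An [hbond_criteria()].
#' @return Occupancy percentage in `[0, 100]`, with attribute `"series"`
#'   (logical per-frame bond presence).
#' @export
hbond_occupancy <- function(traj, donor, acceptor,
                            criteria = hbond_criteria()) {
  stopifnot(inherits(traj, "trajectory"))
  d <- .resolve_selection(traj, donor, single = TRUE, what = "donor")
  a <- .resolve_selection(traj, acceptor, single = TRUE, what = "acceptor")
  present <- vapply(traj$frames, function(fr) {
    hb <- suppressWarnings(detect_hbonds(traj$topology, coords = fr,
                                         criteria = criteria))
    any(hb$donor == d & hb$acceptor == a)
  }, logical(1))
  structure(100 * mean(present), series = present)
}

# Ring geometry and pi-stacking ----------------------------------------------

#' Centroid and best-fit plane normal of a ring
#'
#' Least-squares plane through the atoms; the normal's sign is
#' canonicalised toward +z (ties broken toward +y, then +x).
#'
#' @param coords n x 3 matrix of ring atom coordinates (n >= 3,
#'   non-collinear).
#' @return List with `centroid` (length 3) and `normal` (unit length 3).
#' @export
ring_geometry <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3L) stop("a ring needs at least 3 atoms")
  centroid <- colMeans(coords)
  centered <- sweep(coords, 2, centroid)
  sv <- svd(centered)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12))
    stop("collinear ring atoms; plane undefined")
  normal <- sv$v[, 3L]
  flip <- if (abs(normal[3]) > 1e-12) normal[3] < 0
          else if (abs(normal[2]) > 1e-12) normal[2] < 0
          else normal[1] < 0
  if (flip) normal <- -normal
  list(centroid = centroid, normal = normal / sqrt(sum(normal^2)))
}

#' Aromatic ring stacking metrics over a trajectory
#'
#' Per frame, computes the centroid-centroid distance and the acute angle
#' between the two ring planes; a frame is *stacked* when both are within
#' the thresholds. The verdict is `stacked` when at least half of the
#' frames are.
#'
#' @param traj A `trajectory`.
#' @param ringA,ringB Atom selections (indices or filter lists) of the two
#'   rings.
#' @param distance_threshold Maximum stacked centroid distance in Angstrom
#'   (default 5.0).
#' @param angle_threshold Maximum stacked inter-plane angle in degrees
#'   (default 30).
#' @return An object of class `stacking_report`: mean/SD centroid distance,
#'   mean/SD inter-plane angle, `stacked_fraction`, `verdict`, and the
#'   per-frame `distance`/`angle` series. SDs are population SDs.
#' @export
stacking_metrics <- function(traj, ringA, ringB, distance_threshold = 5.0,
                             angle_threshold = 30) {
  stopifnot(inherits(traj, "trajectory"))
  ia <- .resolve_selection(traj, ringA, what = "ringA")
  ib <- .resolve_selection(traj, ringB, what = "ringB")
  n <- traj$n_frames
  dist <- ang <- numeric(n)
  for (k in seq_len(n)) {
    ga <- tryCatch(ring_geometry(traj$frames[[k]][ia, , drop = FALSE]),
                   error = function(e) stop("frame ", k, ": ",
                                            conditionMessage(e)))
    gb <- tryCatch(ring_geometry(traj$frames[[k]][ib, , drop = FALSE]),
                   error = function(e) stop("frame ", k, ": ",
                                            conditionMessage(e)))
    dist[k] <- .dist3(ga$centroid, gb$centroid)
    cosang <- abs(sum(ga$normal * gb$normal))
    ang[k] <- acos(pmin(1, cosang)) * 180 / pi
  }
  stacked <- dist <= distance_threshold & ang <= angle_threshold
  frac <- mean(stacked)
  structure(list(
    mean_distance = mean(dist), sd_distance = .pop_sd(dist),
    mean_angle = mean(ang), sd_angle = .pop_sd(ang),
    stacked_fraction = frac,
    verdict = if (frac >= 0.5) "stacked" else "not_stacked",
    distance = dist, angle = ang
  ), class = "stacking_report")
}

#' @export
print.stacking_report <- function(x, ...) {
  cat(sprintf(paste0("Ring stacking over %d frames: centroid distance ",
                     "%.2f +/- %.2f A, inter-plane angle %.1f +/- %.1f deg\n"),
              length(x$distance), x$mean_distance, x$sd_distance,
              x$mean_angle, x$sd_angle))
  cat(sprintf("Stacked fraction %.2f -> verdict: %s\n",
              x$stacked_fraction, x$verdict))
  invisible(x)
}

# population SD (divide by n), matching how trajectory summary statistics
# are conventionally reported
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Pairwise distance statistics over a trajectory
#'
#' Plain Euclidean atom-atom distances per frame (no superposition).
#'
#' @param traj A `trajectory`.
#' @param atomA,atomB Atom index or filter list resolving to exactly one
#'   atom each.
#' @return List with `mean`, `sd` (population SD) and the per-frame
#'   `series`, all in Angstrom.
#' @export
distance_stats <- function(traj, atomA, atomB) {
  stopifnot(inherits(traj, "trajectory"))
  ia <- .resolve_selection(traj, atomA, single = TRUE, what = "atomA")
  ib <- .resolve_selection(traj, atomB, single = TRUE, what = "atomB")
  series <- vapply(traj$frames, function(fr) .dist3(fr[ia, ], fr[ib, ]),
                   numeric(1))
  list(mean = mean(series), sd = .pop_sd(series), series = series)
}
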
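# Seeded generators with known ground truth ----------------------------------
#
# Ground truths are computed here by straight-line closed-form code, kept
# textually separate from the analysis modules, so generator output can act
# as an independent oracle for the scoring and geometry pipelines.

# local residue->category lookup, deliberately duplicated from the scoring
# module to preserve oracle independence
.gen_categories <- list(
  aliphatic = c("A", "V", "L", "I", "M", "C"),
  aromatic  = c("F", "W", "Y", "H"),
  polar     = c("S", "T", "N", "Q"),
  positive  = c("K", "R"),
  negative  = c("D", "E"),
  special   = c("G", "P"))

.gen_cat_of <- local({
  lk <- rep(names(.gen_categories), lengths(.gen_categories))
  names(lk) <- unlist(.gen_categories)
  lk
})

#' Recipe for a synthetic alignment with planted deviant residues
#'
#' Describes an alignment of `n_homologs` homolog rows plus one ungapped
#' query: per column, homolog residues are drawn from a category
#' distribution (uniform within the category); the query carries a residue
#' of the realised modal category everywhere except at *planted* positions,
#' where it carries a residue of the planted (deviant) category.
#'
#' @param length Number of alignment columns.
#' @param n_homologs Number of homolog sequences (default 23, a typical
#'   structural-neighbour panel size).
#' @param planted Optional data frame with columns `position` and
#'   `category` naming the deviant query positions.
#' @param column_distributions Optional list (one named probability vector
#'   over the six categories per column). By default each column gets a
#'   two-category mixture: a randomly chosen dominant category at
#'   `dominant_weight` and a second category at the remainder.
#' @param dominant_weight Weight of the dominant category in the default
#'   per-column mixture (default 0.87, i.e. roughly a 20:3 split over 23
#'   homologs).
#' @param gap_prob Per-column homolog gap probability (scalar or length
#'   `length`; default 0).
#' @param allow_infinite If `FALSE`, a planted deviant landing in a
#'   realised zero-entropy column (infinite score) is an error (default
#'   `TRUE`).
#' @param seed Integer seed; the same seed always reproduces the same
#'   alignment.
#' @return An object of class `alignment_recipe`.
#' @export
alignment_recipe <- function(length, n_homologs = 23, planted = NULL,
                             column_distributions = NULL,
                             dominant_weight = 0.87, gap_prob = 0,
                             allow_infinite = TRUE, seed = 1) {
  stopifnot(length >= 1, n_homologs >= 2,
            dominant_weight > 0.5, dominant_weight < 1)
  if (!is.null(planted)) {
    stopifnot(is.data.frame(planted),
              all(c("position", "category") %in% names(planted)))
    if (any(planted$position < 1 | planted$position > length))
      stop("planted positions must lie within the alignment length")
    if (!all(planted$category %in% names(.gen_categories)))
      stop("unknown planted category")
    if (anyDuplicated(planted$position))
      stop("duplicate planted positions")
  }
  if (!is.null(column_distributions)) {
    stopifnot(is.list(column_distributions),
              base::length(column_distributions) == length)
    ok <- vapply(column_distributions, function(p)
      abs(sum(p) - 1) < 1e-9 && all(names(p) %in% names(.gen_categories)),
      logical(1))
    if (!all(ok)) stop("column distributions must sum to 1 over the six categories")
  }
  gap_prob <- rep_len(gap_prob, length)
  stopifnot(all(gap_prob >= 0), all(gap_prob < 1))
  structure(list(length = length, n_homologs = n_homologs,
                 planted = planted,
                 column_distributions = column_distributions,
                 dominant_weight = dominant_weight, gap_prob = gap_prob,
                 allow_infinite = allow_infinite, seed = as.integer(seed)),
            class = "alignment_recipe")
}

#' Generate a synthetic alignment with ground-truth exceptionality scores
#'
#' @param recipe An [alignment_recipe()].
#' @return List with `alignment` (an [alignment()]; homolog ids
#'   `homolog_01`, ... plus a `query` row), `truth` (data frame of the
#'   closed-form per-position score, category, `p_i`, `p_max`, entropy and
#'   status, computed independently of the scoring module) and `recipe`.
#' @export
gen_alignment <- function(recipe) {
  stopifnot(inherits(recipe, "alignment_recipe"))
  set.seed(recipe$seed)
  L <- recipe$length; n <- recipe$n_homologs
  cats <- names(.gen_categories)
  dists <- recipe$column_distributions
  if (is.null(dists)) {
    dists <- lapply(seq_len(L), function(l) {
      pick <- sample(cats, 2L)
      p <- c(recipe$dominant_weight, 1 - recipe$dominant_weight)
      names(p) <- pick
      p
    })
  }
  planted_pos <- if (is.null(recipe$planted)) integer(0)
                 else recipe$planted$position
  hom <- matrix("-", nrow = n, ncol = L)
  query <- character(L)
  truth <- vector("list", L)
  for (l in seq_len(L)) {
    p <- dists[[l]]
    drawn_cat <- sample(names(p), n, replace = TRUE, prob = p)
    res <- vapply(drawn_cat, function(cc) {
      set <- .gen_categories[[cc]]
      set[sample.int(base::length(set), 1L)]
    }, character(1))
    gap <- runif(n) < recipe$gap_prob[l]
    res[gap] <- "-"
    hom[, l] <- res

    # closed-form truth from the realised (non-gap) homolog column
    obs <- res[res != "-"]
    counts <- table(factor(unname(.gen_cat_of[obs]), levels = cats))
    n_eff <- sum(counts)
    gap_frac <- mean(res == "-")
    masked <- gap_frac > 0.5 || n_eff == 0L
    props <- if (n_eff > 0L) as.numeric(counts) / n_eff else rep(0, 6)
    names(props) <- cats
    pp <- props[props > 0]
    s <- if (masked || base::length(pp) == 0L) 0 else -sum(pp * log(pp))
    p_max <- if (n_eff > 0L) max(props) else NA_real_
    modal_cat <- if (n_eff > 0L) cats[which.max(props)] else names(p)[1L]

    if (l %in% planted_pos) {
      qcat <- recipe$planted$category[match(l, planted_pos)]
    } else {
      qcat <- modal_cat
    }
    query[l] <- .gen_categories[[qcat]][1L]
    p_i <- unname(props[qcat])
    num <- p_max - p_i
    if (masked) {
      status <- "masked"; score <- NA_real_
    } else if (num == 0) {
      status <- "zero"; score <- 0
    } else if (s == 0) {
      status <- "infinite"; score <- Inf
      if (l %in% planted_pos && !recipe$allow_infinite)
        stop("planted deviant at position ", l, " fell in a zero-entropy ",
             "column; set allow_infinite = TRUE or change the recipe/seed")
    } else {
      status <- "finite"; score <- num / s
    }
    truth[[l]] <- data.frame(position = l, residue = query[l],
                             category = qcat, planted = l %in% planted_pos,
                             p_i = p_i, p_max = p_max, entropy = s,
                             score = score, status = status,
                             stringsAsFactors = FALSE)
  }
  ids <- c(sprintf("homolog_%02d", seq_len(n)), "query")
  seqs <- c(apply(hom, 1L, paste, collapse = ""),
            paste(query, collapse = ""))
  list(alignment = alignment(ids, seqs),
       truth = do.call(rbind, truth), recipe = recipe)
}

#' Generate a synthetic E-value panel with a planted winning family
#'
#' For each protein the planted winner's E-value is drawn below
#' `alpha / 10^separation`, the runner-up at `winner * 10^separation * u`
#' with `u` uniform in `[0.8, 1.2]`, and all other families are either
#' missing or non-significant (E in (0.06, 1)).
#'
#' @param n_families,n_proteins Panel dimensions (`n_families >= 3`).
#' @param winner Planted winning family index (default 1).
#' @param separation Planted order-of-magnitude separation `m >= 1`.
#' @param alpha Significance threshold (default 0.05).
#' @param missing_prob Probability that a non-winner cell is missing
#'   (default 0.3).
#' @param unassigned Indices of proteins whose entire column is missing
#'   (ground truth "unassigned").
#' @param seed Integer seed.
#' @return List with `table` (an [evalue_table()]) and `truth` (data frame
#'   with `protein`, `family`, `separation`, `assigned`).
#' @export
gen_evalue_table <- function(n_families = 7, n_proteins = 4, winner = 1,
                             separation = 7, alpha = 0.05,
                             missing_prob = 0.3, unassigned = integer(0),
                             seed = 1) {
  stopifnot(n_families >= 3, n_proteins >= 1, alpha > 0)
  if (separation < 1) stop("'separation' must be at least 1")
  winner <- as.integer(winner)
  stopifnot(winner >= 1, winner <= n_families)
  set.seed(as.integer(seed))
  families <- sprintf("FAM%02d", seq_len(n_families))
  proteins <- sprintf("prot_%02d", seq_len(n_proteins))
  ev <- matrix(NA_real_, n_families, n_proteins)
  truth <- vector("list", n_proteins)
  for (j in seq_len(n_proteins)) {
    if (j %in% unassigned) {
      truth[[j]] <- data.frame(protein = proteins[j],
                               family = NA_character_,
                               separation = NA_integer_, assigned = FALSE,
                               stringsAsFactors = FALSE)
      next
    }
    best <- 10^runif(1, log10(alpha) - separation - 4,
                     log10(alpha) - separation - 0.5)
    runner_row <- sample(setdiff(seq_len(n_families), winner), 1L)
    ev[winner, j] <- best
    ev[runner_row, j] <- best * 10^separation * runif(1, 0.8, 1.2)
    for (i in setdiff(seq_len(n_families), c(winner, runner_row)))
      if (runif(1) >= missing_prob) ev[i, j] <- runif(1, 0.06, 1.0)
    truth[[j]] <- data.frame(protein = proteins[j],
                             family = families[winner],
                             separation = as.integer(separation),
                             assigned = TRUE, stringsAsFactors = FALSE)
  }
  list(table = evalue_table(ev, families = families, proteins = proteins),
       truth = do.call(rbind, truth))
}

#' Recipe for a synthetic toy trajectory
#'
#' Schedules are realised exactly, frame by frame: a hydrogen-bond triplet
#' placed inside (2.9 Angstrom donor-acceptor, 5 deg deviation) or outside
#' (3.5 Angstrom, or 45 deg deviation) the detection criteria; an aromatic
#' ring pair at scheduled centroid distance and inter-plane angle; a
#' restrained atom pair placed inside or outside the flat bottom; and an
#' optional free atom pair following a prescribed distance series.
#'
#' @param n_frames Number of frames.
#' @param hbond_schedule Logical vector (`TRUE` = bond present) of length
#'   `n_frames`, or `NULL` to omit the hydrogen-bond group.
#' @param ring_distance,ring_angle Numeric vectors of scheduled centroid
#'   distances (Angstrom) and inter-plane angles (degrees), or `NULL`.
#' @param restraint A [restraint_spec()] paired with `restraint_violating`
#'   (logical vector), or `NULL`.
#' @param restraint_violating Logical vector (`TRUE` = frame outside the
#'   flat bottom).
#' @param pair_distance Either a numeric vector of distances (Angstrom) or
#'   a list `list(mean =, sd =)` describing a Gaussian distance process
#'   realised at generation time, or `NULL`.
#' @param seed Integer seed (used only by stochastic schedules).
#' @return An object of class `trajectory_recipe`.
#' @export
trajectory_recipe <- function(n_frames = 50, hbond_schedule = NULL,
                              ring_distance = NULL, ring_angle = NULL,
                              restraint = NULL, restraint_violating = NULL,
                              pair_distance = NULL, seed = 1) {
  stopifnot(n_frames >= 1)
  chk_len <- function(x, nm) {
    if (!is.null(x) && base::length(x) != n_frames)
      stop("'", nm, "' must have one entry per frame")
  }
  chk_len(hbond_schedule, "hbond_schedule")
  chk_len(ring_distance, "ring_distance")
  chk_len(ring_angle, "ring_angle")
  chk_len(restraint_violating, "restraint_violating")
  if (is.null(ring_distance) != is.null(ring_angle))
    stop("ring_distance and ring_angle must be given together")
  if (is.null(restraint) != is.null(restraint_violating))
    stop("restraint and restraint_violating must be given together")
  if (!is.null(restraint)) stopifnot(inherits(restraint, "restraint_spec"))
  if (!is.null(pair_distance) && !is.list(pair_distance))
    chk_len(pair_distance, "pair_distance")
  if (is.list(pair_distance))
    stopifnot(all(c("mean", "sd") %in% names(pair_distance)))
  structure(list(n_frames = n_frames, hbond_schedule = hbond_schedule,
                 ring_distance = ring_distance, ring_angle = ring_angle,
                 restraint = restraint,
                 restraint_violating = restraint_violating,
                 pair_distance = pair_distance, seed = as.integer(seed)),
            class = "trajectory_recipe")
}

# regular hexagon (radius 1.4 Angstrom) in the xy-plane
.hexagon <- function() {
  th <- (0:5) * pi / 3
  cbind(1.4 * cos(th), 1.4 * sin(th), 0)
}

.rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

# acceptor position realising donor-acceptor distance R and a deviation
# `dev` (deg) from linearity at the hydrogen; donor at origin, H at (1,0,0)
.place_acceptor <- function(R, dev) {
  u <- c(cos(dev * pi / 180), sin(dev * pi / 180), 0)
  t <- -u[1] + sqrt(u[1]^2 - 1 + R^2)
  c(1, 0, 0) + t * u
}

#' Generate a synthetic toy trajectory with known ground truth
#'
#' Builds a multi-model PDB realising the recipe's schedules exactly and
#' returns it together with the closed-form ground truth (computed from the
#' schedules, independently of the analysis functions).
#'
#' @param recipe A [trajectory_recipe()].
#' @param stacking_distance_threshold,stacking_angle_threshold Thresholds
#'   used to derive the ground-truth stacked fraction from the ring
#'   schedules (defaults 5 Angstrom / 30 deg, matching
#'   [stacking_metrics()] defaults).
#' @return List with `pdb` (character vector of multi-model PDB lines),
#'   `trajectory` (the parsed-equivalent `trajectory` object), `truth`
#'   (list of scheduled occupancy/stacking/violation/distance values) and
#'   `recipe`. Atom groups present only when scheduled: donor `N`/`H1`
#'   (SER 1) and acceptor `O` (THR 2); rings PHE 101 and LIG 901; restrained
#'   pair CA of ALA 301/302; free pair PA/PB of LIG 401/402.
#' @export
gen_trajectory <- function(recipe, stacking_distance_threshold = 5.0,
                           stacking_angle_threshold = 30) {
  stopifnot(inherits(recipe, "trajectory_recipe"))
  set.seed(recipe$seed)
  n <- recipe$n_frames
  pair_d <- recipe$pair_distance
  if (is.list(pair_d))
    pair_d <- rnorm(n, mean = pair_d$mean, sd = pair_d$sd)

  atoms <- list(); base_xyz <- list()
  add_atom <- function(name, resname, resno, element) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      serial = length(atoms) + 1L, atom = name, resname = resname,
      resno = resno, chain = "A", element = element,
      stringsAsFactors = FALSE)
  }
  if (!is.null(recipe$hbond_schedule)) {
    add_atom("N", "SER", 1L, "N")
    add_atom("H1", "SER", 1L, "H")
    add_atom("O", "THR", 2L, "O")
  }
  if (!is.null(recipe$ring_distance)) {
    for (nm in c("CG", "CD1", "CE1", "CZ", "CE2", "CD2"))
      add_atom(nm, "PHE", 101L, "C")
    for (nm in sprintf("C%d", 1:6))
      add_atom(nm, "LIG", 901L, "C")
  }
  if (!is.null(recipe$restraint)) {
    add_atom("CA", "ALA", 301L, "C")
    add_atom("CA", "ALA", 302L, "C")
  }
  if (!is.null(pair_d)) {
    add_atom("PA", "LIG", 401L, "P")
    add_atom("PB", "LIG", 402L, "P")
  }
  if (length(atoms) == 0L) stop("recipe schedules nothing to generate")
  at <- do.call(rbind, atoms)

  frames <- vector("list", n)
  unbonded_seen <- 0L
  for (k in seq_len(n)) {
    xyz <- matrix(NA_real_, nrow(at), 3L)
    row <- 1L
    if (!is.null(recipe$hbond_schedule)) {
      xyz[1L, ] <- c(0, 0, 0)
      xyz[2L, ] <- c(1, 0, 0)
      if (recipe$hbond_schedule[k]) {
        xyz[3L, ] <- .place_acceptor(2.9, 5)
      } else {
        unbonded_seen <- unbonded_seen + 1L
        xyz[3L, ] <- if (unbonded_seen %% 2L == 1L)
          .place_acceptor(3.5, 5) else .place_acceptor(2.9, 45)
      }
      row <- 4L
    }
    if (!is.null(recipe$ring_distance)) {
      hexA <- sweep(.hexagon(), 2, c(-30, 0, 0), `+`)
      hexB <- .hexagon() %*% t(.rot_x(recipe$ring_angle[k]))
      hexB <- sweep(hexB, 2, c(-30, 0, recipe$ring_distance[k]), `+`)
      xyz[row:(row + 5L), ] <- hexA
      xyz[(row + 6L):(row + 11L), ] <- hexB
      row <- row + 12L
    }
    if (!is.null(recipe$restraint)) {
      rs <- recipe$restraint
      d_nm <- if (recipe$restraint_violating[k]) rs$r1_nm + 0.35
              else rs$r_init_nm
      xyz[row, ] <- c(30, 0, 0)
      xyz[row + 1L, ] <- c(30 + d_nm * 10, 0, 0)
      row <- row + 2L
    }
    if (!is.null(pair_d)) {
      xyz[row, ] <- c(30, 30, 0)
      xyz[row + 1L, ] <- c(30, 30 + pair_d[k], 0)
    }
    dm <- as.matrix(stats::dist(xyz))
    if (min(dm[upper.tri(dm)]) < 0.8)
      stop("geometric infeasibility in frame ", k,
           ": atoms closer than 0.8 Angstrom")
    frames[[k]] <- xyz
  }

  topo <- structure(list(atoms = at,
                         coords = `colnames<-`(frames[[1L]],
                                               c("x", "y", "z"))),
                    class = "structure")
  traj <- structure(list(topology = topo, frames = frames, n_frames = n),
                    class = "trajectory")

  truth <- list()
  if (!is.null(recipe$hbond_schedule))
    truth$hbond_occupancy_pct <- 100 * mean(recipe$hbond_schedule)
  if (!is.null(recipe$ring_distance)) {
    stacked <- recipe$ring_distance <= stacking_distance_threshold &
      recipe$ring_angle <= stacking_angle_threshold
    truth$stacked_fraction <- mean(stacked)
    truth$ring_mean_distance <- mean(recipe$ring_distance)
    truth$ring_mean_angle <- mean(recipe$ring_angle)
    truth$ring_sd_angle <-
      sqrt(mean((recipe$ring_angle - mean(recipe$ring_angle))^2))
  }
  if (!is.null(recipe$restraint))
    truth$restraint_violation_pct <- 100 * mean(recipe$restraint_violating)
  if (!is.null(pair_d)) {
    truth$pair_mean_distance <- mean(pair_d)
    truth$pair_sd_distance <- sqrt(mean((pair_d - mean(pair_d))^2))
  }

  list(pdb = write_trajectory_pdb(traj), trajectory = traj, truth = truth,
       recipe = recipe)
}
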
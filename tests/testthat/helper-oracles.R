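# Independent brute-force oracles used across the suite. These deliberately
# re-derive every quantity with plain loops and their own lookup tables so
# they share no code path with the package implementation.

oracle_categories <- list(
  aliphatic = c("A", "V", "L", "I", "M", "C"),
  aromatic  = c("F", "W", "Y", "H"),
  polar     = c("S", "T", "N", "Q"),
  positive  = c("K", "R"),
  negative  = c("D", "E"),
  special   = c("G", "P"))

oracle_cat_lookup <- function(ch) {
  for (nm in names(oracle_categories))
    if (ch %in% oracle_categories[[nm]]) return(nm)
  NA_character_
}

# exhaustive-counting oracle for one column: homolog residue characters plus
# the query residue -> proportions, entropy (nats), score, status
oracle_column <- function(homologs, query_res, max_gap = 0.5) {
  n_gap <- 0L
  counts <- setNames(rep(0L, 6), names(oracle_categories))
  for (ch in homologs) {
    if (ch == "-") { n_gap <- n_gap + 1L; next }
    cat <- oracle_cat_lookup(ch)
    if (!is.na(cat)) counts[cat] <- counts[cat] + 1L
  }
  gap_fraction <- n_gap / length(homologs)
  n_eff <- sum(counts)
  masked <- gap_fraction > max_gap || n_eff == 0L
  props <- if (n_eff > 0) counts / n_eff else counts * 0
  s <- 0
  if (!masked) for (p in props) if (p > 0) s <- s - p * log(p)
  p_max <- if (n_eff > 0) max(props) else NA_real_
  qcat <- oracle_cat_lookup(query_res)
  p_i <- if (is.na(qcat)) 0 else unname(props[qcat])
  if (masked) {
    score <- NA_real_; status <- "masked"
  } else if (p_max - p_i == 0) {
    score <- 0; status <- "zero"
  } else if (s == 0) {
    score <- Inf; status <- "infinite"
  } else {
    score <- (p_max - p_i) / s; status <- "finite"
  }
  list(proportions = props, gap_fraction = gap_fraction, n_effective = n_eff,
       entropy = s, p_max = p_max, p_i = p_i, score = score, status = status)
}

# build a one-column alignment (homolog rows + query row named "query")
one_column_alignment <- function(homologs, query_res) {
  alignment(c(sprintf("h%03d", seq_along(homologs)), "query"),
            c(homologs, query_res))
}

# exhaustive rotation-grid oracle for superposition RMSD: iteratively
# refined search over the rotation vector (axis * angle; Rodrigues formula),
# after centroid alignment. The rotation-vector chart is degeneracy-free, so
# coarse-to-fine refinement cannot get trapped the way Euler angles can.
oracle_grid_rmsd <- function(mobile, reference, iters = 8, pts = 13) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  rot_vec <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-14) return(diag(3))
    u <- v / th
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  center <- c(0, 0, 0); width <- pi
  best <- Inf
  for (it in seq_len(iters)) {
    g1 <- seq(center[1] - width, center[1] + width, length.out = pts)
    g2 <- seq(center[2] - width, center[2] + width, length.out = pts)
    g3 <- seq(center[3] - width, center[3] + width, length.out = pts)
    for (a in g1) for (b in g2) for (cc in g3) {
      R <- rot_vec(c(a, b, cc))
      v <- sqrt(mean(rowSums((A %*% t(R) - B)^2)))
      if (v < best) { best <- v; center <- c(a, b, cc) }
    }
    width <- width * 2.5 / (pts - 1)
  }
  best
}

# all-pairs hydrogen-bond oracle with plain loops (donors/acceptors are N
# and O; hydrogen belongs to the nearest heavy N/O within 1.2 Angstrom)
oracle_hbonds <- function(elements, xyz, dist_cutoff = 3.0,
                          angle_cutoff = 30) {
  d3 <- function(i, j) sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  heavy <- which(elements %in% c("N", "O"))
  found <- list()
  for (h in which(elements == "H")) {
    don <- NA_integer_; dmin <- Inf
    for (i in heavy) {
      d <- d3(h, i)
      if (d < dmin) { dmin <- d; don <- i }
    }
    if (!is.finite(dmin) || dmin > 1.2) next
    for (acc in heavy) {
      if (acc == don) next
      if (d3(don, acc) > dist_cutoff) next
      v1 <- xyz[don, ] - xyz[h, ]; v2 <- xyz[acc, ] - xyz[h, ]
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                (sqrt(sum(v1^2)) * sqrt(sum(v2^2))))))
      if (180 - ang * 180 / pi > angle_cutoff) next
      found[[length(found) + 1L]] <- c(donor = don, hydrogen = h,
                                       acceptor = acc)
    }
  }
  if (length(found) == 0L)
    return(matrix(integer(0), ncol = 3,
                  dimnames = list(NULL, c("donor", "hydrogen", "acceptor"))))
  do.call(rbind, found)
}

# random rigid transform (proper rotation + translation)
random_rigid <- function() {
  M <- matrix(rnorm(9), 3, 3)
  q <- qr.Q(qr(M))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  list(R = q, t = rnorm(3, sd = 10))
}

apply_rigid <- function(x, tf) sweep(x %*% t(tf$R), 2, -tf$t)

# planted-deviant recipe where every planted category is guaranteed absent
# from its column's two-category mixture (keeps the score margin >= 0.5)
make_planted_recipe <- function(seed, length = 30, n_planted = 2) {
  set.seed(seed * 1000L + 17L)
  cats <- names(oracle_categories)
  dists <- lapply(seq_len(length), function(l) {
    pick <- sample(cats, 2L)
    setNames(c(0.87, 0.13), pick)
  })
  pos <- sort(sample.int(length, n_planted))
  planted_cat <- vapply(pos, function(l)
    sample(setdiff(cats, names(dists[[l]])), 1L), character(1))
  alignment_recipe(length = length, n_homologs = 23,
                   planted = data.frame(position = pos,
                                        category = planted_cat,
                                        stringsAsFactors = FALSE),
                   column_distributions = dists, seed = seed)
}
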
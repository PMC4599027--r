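# Per-residue exceptionality scoring over physicochemical categories --------

#' The six physicochemical amino-acid categories
#'
#' Partition of the 20 standard residues used throughout the exceptionality
#' score: aliphatic \{A,V,L,I,M,C\}, aromatic \{F,W,Y,H\}, polar \{S,T,N,Q\},
#' positive \{K,R\}, negative \{D,E\}, special \{G,P\}.
#'
#' @return Named list of character vectors; the sets are disjoint and cover
#'   the 20 standard residues exactly.
#' @export
amino_acid_categories <- function() {
  list(aliphatic = c("A", "V", "L", "I", "M", "C"),
       aromatic  = c("F", "W", "Y", "H"),
       polar     = c("S", "T", "N", "Q"),
       positive  = c("K", "R"),
       negative  = c("D", "E"),
       special   = c("G", "P"))
}

# flat lookup: residue -> category name
.category_of <- local({
  cats <- list(aliphatic = c("A", "V", "L", "I", "M", "C"),
               aromatic  = c("F", "W", "Y", "H"),
               polar     = c("S", "T", "N", "Q"),
               positive  = c("K", "R"),
               negative  = c("D", "E"),
               special   = c("G", "P"))
  lookup <- rep(names(cats), lengths(cats))
  names(lookup) <- unlist(cats)
  lookup
})

#' Physicochemical category of a residue
#'
#' @param aa Character vector of single one-letter residue codes.
#' @return Category name per residue (`"aliphatic"`, `"aromatic"`,
#'   `"polar"`, `"positive"`, `"negative"`, `"special"`), or `NA` for gaps
#'   and ambiguity codes.
#' @export
#' @examples
#' residue_category(c("C", "H", "X"))  # aliphatic, aromatic, NA
residue_category <- function(aa) {
  aa <- as.character(aa)
  if (any(nchar(aa) != 1L))
    stop("residue codes must be single characters")
  unname(.category_of[toupper(aa)])
}

#' Category entropy of a proportion vector
#'
#' Shannon entropy `-sum(p * log(p))` over the categories with `p > 0`
#' (null categories are ignored). Natural log by default; the base only
#' rescales scores and never changes rankings.
#'
#' @param p Numeric vector of category proportions (should sum to 1).
#' @param base Logarithm base (default `exp(1)`, i.e. nats).
#' @return Non-negative entropy; 0 when at most one category is present.
#' @export
category_entropy <- function(p, base = exp(1)) {
  p <- p[p > 0]
  if (length(p) == 0L) return(0)
  -sum(p * log(p)) / log(base)
}

#' Category profile of an alignment column
#'
#' Computes the per-category proportions `P_i(l)` at column `l` over the
#' homolog rows (the query is excluded by default), the gap fraction of
#' those rows, and the category entropy `s(l)`. Gaps and ambiguity codes are
#' excluded from both numerator and denominator of the proportions. When the
#' column holds more than `max_gap_fraction` gaps the profile is *masked*
#' and its entropy set to 0.
#'
#' @param aln An [alignment()].
#' @param query_id Identifier of the query sequence.
#' @param l 1-based column index.
#' @param include_query Count the query row into the proportions as well
#'   (default `FALSE`; exposed for sensitivity checks).
#' @param max_gap_fraction Gap fraction above which the column is masked
#'   (default 0.5, strict `>`).
#' @param base Logarithm base for the entropy.
#' @return An object of class `column_profile` with elements `proportions`
#'   (named, over the six categories), `gap_fraction`, `n_effective`,
#'   `entropy`, `p_max` and `masked`.
#' @export
column_profile <- function(aln, query_id, l, include_query = FALSE,
                           max_gap_fraction = 0.5, base = exp(1)) {
  stopifnot(inherits(aln, "alignment"))
  if (!query_id %in% aln$ids) stop("unknown query id: ", query_id)
  l <- as.integer(l)
  if (l < 1L || l > aln$length)
    stop("column index out of range [1, ", aln$length, "]")
  m <- aln_matrix(aln)
  rows <- if (include_query) aln$ids else setdiff(aln$ids, query_id)
  col <- m[rows, l]
  gap_fraction <- if (length(col)) mean(col == "-") else 1
  cats <- residue_category(ifelse(col == "-", "X", col))
  counts <- table(factor(cats, levels = names(amino_acid_categories())))
  n_eff <- sum(counts)
  masked <- gap_fraction > max_gap_fraction
  if (n_eff == 0L && !masked) {
    warning("column ", l, " has no categorisable residues; profile masked")
    masked <- TRUE
  }
  props <- if (n_eff > 0L) as.numeric(counts) / n_eff else rep(0, 6)
  names(props) <- names(counts)
  structure(list(
    column = l,
    proportions = props,
    gap_fraction = gap_fraction,
    n_effective = as.integer(n_eff),
    entropy = if (masked) 0 else category_entropy(props, base = base),
    p_max = if (n_eff > 0L) max(props) else NA_real_,
    masked = masked
  ), class = "column_profile")
}

#' @export
print.column_profile <- function(x, ...) {
  cat("Column ", x$column, ": n_eff = ", x$n_effective,
      ", gap fraction = ", signif(x$gap_fraction, 3),
      ", entropy = ", signif(x$entropy, 4),
      if (x$masked) " [masked: >50% gaps]" else "", "\n", sep = "")
  print(round(x$proportions, 3))
  invisible(x)
}

#' Entropy of a column profile
#'
#' @param profile A [column_profile()].
#' @return The category entropy `s(l)`; 0 for a masked profile (gap rule).
#' @export
column_entropy <- function(profile) {
  stopifnot(inherits(profile, "column_profile"))
  profile$entropy
}

#' Exceptionality score of the query residue at one column
#'
#' `S(l) = (P_max(l) - P_i(l)) / s(l)` where `P_i(l)` is the proportion of
#' the query residue's physicochemical category among the homologs at column
#' `l`, `P_max(l)` the proportion of the most abundant (expected) category,
#' and `s(l)` the category entropy. A large score marks a query residue
#' whose category is unexpected at a conserved position.
#'
#' @inheritParams column_profile
#' @return A list with `value` and `status`:
#'   * `finite` — ordinary score `>= 0`;
#'   * `zero` — the query category attains `P_max` (numerator 0);
#'   * `infinite` — deviant query at a zero-entropy (fully conserved) column;
#'   * `masked` — the >50 %-gap rule fired; `value` is `NA`.
#' @export
exceptionality_score <- function(aln, query_id, l, include_query = FALSE,
                                 max_gap_fraction = 0.5, base = exp(1)) {
  prof <- column_profile(aln, query_id, l, include_query = include_query,
                         max_gap_fraction = max_gap_fraction, base = base)
  qres <- aln_matrix(aln)[query_id, l]
  if (qres == "-")
    stop("internal error: query has a gap at column ", l,
         " (mask query insertions first)")
  if (prof$masked) return(list(value = NA_real_, status = "masked"))
  qcat <- residue_category(qres)
  p_i <- if (is.na(qcat)) 0 else unname(prof$proportions[qcat])
  num <- prof$p_max - p_i
  if (num == 0) list(value = 0, status = "zero")
  else if (prof$entropy == 0) list(value = Inf, status = "infinite")
  else list(value = num / prof$entropy, status = "finite")
}

#' Per-residue exceptionality profile of a query sequence
#'
#' Hides alignment columns where the query has a gap, then scores every
#' remaining column with [exceptionality_score()]. Positions are numbered
#' 1-based along the ungapped query, matching residue numbering.
#'
#' @inheritParams column_profile
#' @return A data frame of class `exceptionality_profile` with one row per
#'   query residue: `position`, `column` (original alignment column),
#'   `residue`, `category`, `p_i`, `p_max`, `n_effective`, `entropy`,
#'   `score`, `status`.
#' @export
exceptionality_profile <- function(aln, query_id, include_query = FALSE,
                                   max_gap_fraction = 0.5, base = exp(1)) {
  stopifnot(inherits(aln, "alignment"))
  if (!query_id %in% aln$ids) stop("unknown query id: ", query_id)
  masked <- mask_query_insertions(aln, query_id)
  sub <- masked$alignment
  qchars <- strsplit(sub$seqs[sub$ids == query_id], "")[[1]]
  n <- sub$length
  rows <- lapply(seq_len(n), function(j) {
    prof <- column_profile(sub, query_id, j, include_query = include_query,
                           max_gap_fraction = max_gap_fraction, base = base)
    sc <- exceptionality_score(sub, query_id, j,
                               include_query = include_query,
                               max_gap_fraction = max_gap_fraction,
                               base = base)
    qcat <- residue_category(qchars[j])
    data.frame(position = j, column = masked$mask$kept[j],
               residue = qchars[j],
               category = ifelse(is.na(qcat), "none", qcat),
               p_i = if (is.na(qcat)) 0 else unname(prof$proportions[qcat]),
               p_max = prof$p_max, n_effective = prof$n_effective,
               entropy = prof$entropy, score = sc$value, status = sc$status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(position = integer(0), column = integer(0),
                      residue = character(0), category = character(0),
                      p_i = numeric(0), p_max = numeric(0),
                      n_effective = integer(0), entropy = numeric(0),
                      score = numeric(0), status = character(0))
  attr(out, "query_id") <- query_id
  class(out) <- c("exceptionality_profile", "data.frame")
  out
}

#' Rank the most exceptional residues
#'
#' Orders the profile with infinite-score positions first, then finite
#' scores descending, ties broken by ascending position; masked positions
#' sort last. Returns the top `k` rows.
#'
#' @param profile An [exceptionality_profile()].
#' @param k Number of positions to report (`k >= 1`). If `k` exceeds the
#'   number of positions, all are returned with a message.
#' @return A data frame of class `exceptionality_report`.
#' @export
rank_exceptional <- function(profile, k) {
  stopifnot(inherits(profile, "exceptionality_profile"), k >= 1)
  df <- as.data.frame(profile)
  # zero-status rows carry score 0 so they interleave correctly with finites
  score_key <- ifelse(is.na(df$score), -Inf,
                      ifelse(is.infinite(df$score), Inf, df$score))
  ord <- order(ifelse(df$status == "masked", 1L, 0L), -score_key,
               df$position)
  df <- df[ord, , drop = FALSE]
  if (k > nrow(df)) {
    message("requested top ", k, " but profile has only ", nrow(df),
            " positions; returning all")
    k <- nrow(df)
  }
  out <- df[seq_len(k), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "query_id") <- attr(profile, "query_id")
  class(out) <- c("exceptionality_report", "data.frame")
  out
}

#' @export
print.exceptionality_report <- function(x, digits = 4, ...) {
  cat("Top exceptional residues for query '", attr(x, "query_id"), "':\n",
      sep = "")
  df <- as.data.frame(x)
  df$p_i <- round(df$p_i, digits); df$p_max <- round(df$p_max, digits)
  df$entropy <- round(df$entropy, digits); df$score <- round(df$score, digits)
  print(df[, c("position", "residue", "category", "p_i", "p_max",
               "entropy", "score", "status")], row.names = FALSE)
  invisible(x)
}
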
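# Profile-HMM E-value panel classification -----------------------------------

#' Construct an E-value table
#'
#' Families x proteins matrix of profile-HMM search E-values. A missing
#' entry (`NA`) means "no significant hit reported".
#'
#' @param evalues Numeric matrix (families in rows, proteins in columns);
#'   present entries must be positive.
#' @param families Character vector of family/model identifiers (row names).
#' @param proteins Character vector of protein identifiers (column names).
#' @param family_names Optional descriptive family names.
#' @return An object of class `evalue_table`.
#' @export
evalue_table <- function(evalues, families = rownames(evalues),
                         proteins = colnames(evalues), family_names = NULL) {
  evalues <- as.matrix(evalues)
  if (is.null(families) || is.null(proteins))
    stop("family and protein identifiers are required")
  if (length(families) != nrow(evalues) || length(proteins) != ncol(evalues))
    stop("identifier lengths do not match the matrix dimensions")
  if (nrow(evalues) == 0L || ncol(evalues) == 0L)
    stop("empty E-value table")
  if (any(evalues[!is.na(evalues)] <= 0))
    stop("E-values must be positive")
  dimnames(evalues) <- list(families, proteins)
  structure(list(families = families, proteins = proteins,
                 family_names = family_names, evalues = evalues),
            class = "evalue_table")
}

#' @export
print.evalue_table <- function(x, ...) {
  cat("E-value table: ", length(x$families), " families x ",
      length(x$proteins), " proteins (", sum(is.na(x$evalues)),
      " missing)\n", sep = "")
  print(signif(x$evalues, 3), na.print = "-")
  invisible(x)
}

#' Read an E-value table from TSV
#'
#' Expected layout: a header row naming the protein columns; a leading
#' `family` column of model ids, and optionally a `name` column of
#' descriptive names. Cells that are empty, `-` or an en-dash are missing.
#'
#' @param source File path, single string, or character vector of lines.
#' @return An [evalue_table()].
#' @export
read_evalue_table <- function(source) {
  lines <- .source_lines(source)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("empty E-value table")
  df <- read.delim(text = paste(lines, collapse = "\n"),
                   colClasses = "character", check.names = FALSE)
  if (!"family" %in% names(df))
    stop("E-value TSV must have a leading 'family' column")
  families <- df$family
  family_names <- if ("name" %in% names(df)) df$name else NULL
  prot_cols <- setdiff(names(df), c("family", "name"))
  if (length(prot_cols) == 0L) stop("no protein columns found")
  ev <- matrix(NA_real_, nrow = nrow(df), ncol = length(prot_cols))
  for (j in seq_along(prot_cols)) {
    raw <- trimws(df[[prot_cols[j]]])
    missing <- raw %in% c("", "-", "–", "—", "NA")
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!missing & is.na(val))
    if (length(bad) > 0L)
      stop("non-numeric E-value '", raw[bad[1L]], "' at family ",
           families[bad[1L]], ", protein ", prot_cols[j])
    ev[, j] <- ifelse(missing, NA_real_, val)
  }
  evalue_table(ev, families = families, proteins = prot_cols,
               family_names = family_names)
}

#' Significant entries of an E-value table
#'
#' @param table An [evalue_table()].
#' @param alpha Significance threshold (default 0.05). The boundary is
#'   inclusive: `E <= alpha` is significant; missing entries are not.
#' @return Logical matrix of the table's shape.
#' @export
significant_hits <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "evalue_table"), alpha > 0)
  sig <- !is.na(table$evalues) & table$evalues <= alpha
  dimnames(sig) <- dimnames(table$evalues)
  sig
}

#' Order-of-magnitude separation between two E-values
#'
#' `round(log10(second / best))`: how many orders of magnitude the best
#' E-value is below the runner-up.
#'
#' @param best,second Positive E-values with `best <= second`.
#' @return Integer magnitude; `NA` if `second` is missing.
#' @export
#' @examples
#' separation_magnitude(4.9e-12, 3.3e-5)  # 7
separation_magnitude <- function(best, second) {
  if (is.na(second)) return(NA_integer_)
  if (is.na(best) || best <= 0 || second <= 0)
    stop("E-values must be positive")
  if (best > second) stop("'best' must not exceed 'second'")
  as.integer(round(log10(second / best)))
}

#' Assign a protein to the family with the lowest E-value
#'
#' The best family is the `argmin` of the present E-values for the protein;
#' the call is only *assigned* when the best E-value is significant
#' (`<= alpha`). Ties for best are broken by family list order and reported.
#'
#' @param table An [evalue_table()].
#' @param protein Protein identifier (a column of the table).
#' @param alpha Significance threshold (default 0.05, inclusive).
#' @return An object of class `family_call`: `protein`, `assigned`,
#'   `best_family`, `best_evalue`, `second_family`, `second_evalue`,
#'   `separation_magnitude`, `significant`, `tied_best`.
#' @export
assign_family <- function(table, protein, alpha = 0.05) {
  stopifnot(inherits(table, "evalue_table"), alpha > 0)
  if (!protein %in% table$proteins)
    stop("unknown protein: ", protein)
  ev <- table$evalues[, protein]
  present <- which(!is.na(ev))
  if (length(present) == 0L) {
    call <- list(protein = protein, assigned = FALSE,
                 best_family = NA_character_, best_evalue = NA_real_,
                 second_family = NA_character_, second_evalue = NA_real_,
                 separation_magnitude = NA_integer_, significant = FALSE,
                 tied_best = character(0), no_hits = TRUE)
    return(structure(call, class = "family_call"))
  }
  o <- present[order(ev[present])]
  best <- o[1L]
  ties <- present[ev[present] == ev[best]]
  second <- if (length(o) > 1L) o[2L] else NA_integer_
  best_e <- unname(ev[best])
  second_e <- if (is.na(second)) NA_real_ else unname(ev[second])
  sig <- best_e <= alpha
  structure(list(
    protein = protein, assigned = sig,
    best_family = table$families[best], best_evalue = best_e,
    second_family = if (is.na(second)) NA_character_
                    else table$families[second],
    second_evalue = second_e,
    separation_magnitude = separation_magnitude(best_e, second_e),
    significant = sig,
    tied_best = if (length(ties) > 1L) table$families[ties] else character(0),
    no_hits = FALSE
  ), class = "family_call")
}

#' @export
print.family_call <- function(x, ...) {
  if (!x$assigned) {
    cat("Protein ", x$protein, ": unassigned",
        if (x$no_hits) " (no hits)" else
          sprintf(" (best E = %.3g, not significant)", x$best_evalue),
        "\n", sep = "")
    return(invisible(x))
  }
  cat("Protein ", x$protein, " -> family ", x$best_family,
      sprintf(" (E = %.3g", x$best_evalue), sep = "")
  if (!is.na(x$second_family))
    cat(sprintf("; second %s, E = %.3g; separation 10^%d",
                x$second_family, x$second_evalue, x$separation_magnitude))
  cat(")\n")
  if (length(x$tied_best))
    cat("  tie for best among: ", paste(x$tied_best, collapse = ", "), "\n")
  invisible(x)
}

#' Family calls for every protein of a table
#'
#' @inheritParams assign_family
#' @return Data frame with one row per protein.
#' @export
assign_families <- function(table, alpha = 0.05) {
  calls <- lapply(table$proteins, function(p) assign_family(table, p, alpha))
  do.call(rbind, lapply(calls, function(cl)
    data.frame(protein = cl$protein, assigned = cl$assigned,
               best_family = cl$best_family, best_evalue = cl$best_evalue,
               second_family = cl$second_family,
               second_evalue = cl$second_evalue,
               separation_magnitude = cl$separation_magnitude,
               stringsAsFactors = FALSE)))
}
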
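# Alignment container and I/O ------------------------------------------------

# Allowed alignment alphabet: 20 standard residues, common ambiguity codes,
# and the single gap character '-'.
.aln_alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                   c("X", "B", "Z", "U", "O"), "-")

#' Construct a multiple sequence alignment object
#'
#' An `alignment` is an ordered set of equal-length gapped amino-acid
#' sequences with unique identifiers and optional per-column annotation
#' strings (e.g. a Stockholm `#=GC` conservation line).
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param seqs Character vector of aligned sequences (same length as `ids`),
#'   all of identical width, using one-letter residue codes, ambiguity codes
#'   (X, B, Z, U, O) and `-` for gaps.
#' @param column_annotations Optional named list of per-column annotation
#'   strings, each as wide as the alignment.
#' @return An object of class `alignment` with elements `ids`, `seqs`,
#'   `length` (number of columns) and `column_annotations`.
#' @export
#' @examples
#' aln <- alignment(c("a", "b"), c("ACDE", "AC-E"))
#' aln$length
alignment <- function(ids, seqs, column_annotations = NULL) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) == 0L) stop("alignment must contain at least one sequence")
  if (length(ids) != length(seqs))
    stop("'ids' and 'seqs' must have the same length")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  widths <- nchar(seqs)
  if (length(unique(widths)) > 1L) {
    bad <- ids[widths != widths[1L]][1L]
    stop("length mismatch: sequence '", bad, "' has ", nchar(seqs[ids == bad]),
         " columns, expected ", widths[1L])
  }
  chars <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  unknown <- setdiff(chars, .aln_alphabet)
  if (length(unknown) > 0L)
    stop("invalid residue code(s): ", paste(unknown, collapse = ", "))
  if (!is.null(column_annotations)) {
    stopifnot(is.list(column_annotations), !is.null(names(column_annotations)))
    bad <- names(column_annotations)[nchar(unlist(column_annotations)) != widths[1L]]
    if (length(bad) > 0L)
      stop("column annotation '", bad[1L], "' does not span all columns")
  }
  structure(list(ids = ids, seqs = seqs, length = widths[1L],
                 column_annotations = column_annotations),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat("Multiple sequence alignment: ", length(x$ids), " sequences x ",
      x$length, " columns\n", sep = "")
  if (!is.null(x$column_annotations))
    cat("Column annotations:", paste(names(x$column_annotations),
                                     collapse = ", "), "\n")
  invisible(x)
}

# character matrix view (rows = sequences, cols = alignment columns)
aln_matrix <- function(aln) {
  matrix(unlist(strsplit(aln$seqs, ""), use.names = FALSE),
         nrow = length(aln$ids), ncol = aln$length, byrow = TRUE,
         dimnames = list(aln$ids, NULL))
}

# resolve `source` (path, single string with newlines, or vector of lines)
# into a character vector of lines
.source_lines <- function(source) {
  if (length(source) == 1L && !grepl("\n", source) && file.exists(source))
    return(readLines(source, warn = FALSE))
  unlist(strsplit(source, "\n", fixed = TRUE), use.names = FALSE)
}

#' Read a multiple sequence alignment (FASTA or Stockholm)
#'
#' The dialect is auto-detected: files starting with `# STOCKHOLM` are parsed
#' as Stockholm (per-column `#=GC` annotation lines are retained in
#' `column_annotations`; `.` gaps are normalised to `-`), anything else as
#' FASTA.
#'
#' @param source A file path, a single string containing the alignment text,
#'   or a character vector of lines.
#' @return An [alignment()] object.
#' @export
read_alignment <- function(source) {
  lines <- .source_lines(source)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) == 0L]
  nonempty <- lines[nzchar(trimws(lines))]
  if (length(nonempty) == 0L) stop("empty alignment input")
  if (grepl("^# STOCKHOLM", nonempty[1L])) .read_stockholm(lines)
  else .read_fasta(lines)
}

.read_fasta <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("input is neither FASTA nor Stockholm")
  if (!hdr[1L]) stop("FASTA input does not start with a '>' header")
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- sub("\\s.*$", "", ids)
  seqs <- vapply(seq_len(sum(hdr)), function(i) {
    paste(lines[rec == i & !hdr], collapse = "")
  }, character(1))
  alignment(ids, gsub("\\s", "", seqs))
}

# Hand-parsed so that #=GC per-column annotation lines survive (the
# conservation filter needs them); interleaved (multi-block) files supported.
.read_stockholm <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^//", lines)]
  seq_ln <- !grepl("^#", lines) & !grepl("^# STOCKHOLM", lines)
  gc_ln <- grepl("^#=GC\\s", lines)
  seqs <- list()
  anns <- list()
  for (ln in lines[seq_ln]) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L)
      stop("malformed Stockholm sequence line: ", ln)
    seqs[[parts[1L]]] <- paste0(seqs[[parts[1L]]] %||% "", parts[2L])
  }
  for (ln in lines[gc_ln]) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 3L)
      stop("malformed #=GC line: ", ln)
    anns[[parts[2L]]] <- paste0(anns[[parts[2L]]] %||% "", parts[3L])
  }
  if (length(seqs) == 0L) stop("Stockholm input contains no sequences")
  alignment(names(seqs), chartr(".", "-", unlist(seqs)),
            column_annotations = if (length(anns)) anns else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an alignment to FASTA or Stockholm
#'
#' @param aln An [alignment()].
#' @param file Optional path; when `NULL` the lines are returned invisibly
#'   without writing.
#' @param format `"fasta"` or `"stockholm"`. Stockholm output carries the
#'   alignment's `column_annotations` as `#=GC` lines, so a
#'   read-write-read round trip preserves both sequences and annotations.
#' @return Invisibly, the character vector of output lines.
#' @export
write_alignment <- function(aln, file = NULL,
                            format = c("fasta", "stockholm")) {
  stopifnot(inherits(aln, "alignment"))
  format <- match.arg(format)
  lines <- if (format == "fasta") {
    as.vector(rbind(paste0(">", aln$ids), aln$seqs))
  } else {
    w <- max(nchar(aln$ids),
             if (!is.null(aln$column_annotations))
               nchar(paste0("#=GC ", names(aln$column_annotations))) else 0L)
    body <- sprintf("%-*s %s", w, aln$ids, aln$seqs)
    gc <- if (!is.null(aln$column_annotations))
      sprintf("%-*s %s", w,
              paste0("#=GC ", names(aln$column_annotations)),
              unlist(aln$column_annotations)) else character(0)
    c("# STOCKHOLM 1.0", body, gc, "//")
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

# Column masks ----------------------------------------------------------------

#' Column mask bookkeeping
#'
#' Records which original alignment columns survive a masking or filtering
#' step, and why each removed column was dropped.
#'
#' @param kept Strictly increasing integer vector of surviving original
#'   column indices (1-based).
#' @param removed Named character vector: names are removed column indices,
#'   values one of `"query_gap"`, `"gap_fraction"`, `"low_conservation"`.
#' @return An object of class `column_mask`.
#' @export
column_mask <- function(kept, removed = character(0)) {
  kept <- as.integer(kept)
  if (is.unsorted(kept, strictly = TRUE) && length(kept) > 1L)
    stop("'kept' indices must be strictly increasing")
  ridx <- as.integer(names(removed))
  if (length(intersect(kept, ridx)) > 0L)
    stop("kept and removed column sets overlap")
  ok <- c("query_gap", "gap_fraction", "low_conservation")
  if (length(removed) && !all(removed %in% ok))
    stop("unknown removal reason(s): ",
         paste(setdiff(removed, ok), collapse = ", "))
  structure(list(kept = kept, removed = removed), class = "column_mask")
}

#' @export
print.column_mask <- function(x, ...) {
  cat("Column mask: ", length(x$kept), " kept, ", length(x$removed),
      " removed\n", sep = "")
  if (length(x$removed))
    print(table(reason = x$removed))
  invisible(x)
}

# keep a subset of columns (and slice annotations accordingly)
subset_columns <- function(aln, keep) {
  keep <- as.integer(keep)
  m <- aln_matrix(aln)[, keep, drop = FALSE]
  seqs <- apply(m, 1L, paste, collapse = "")
  if (length(keep) == 0L) seqs <- rep("", length(aln$ids))
  anns <- aln$column_annotations
  if (!is.null(anns))
    anns <- lapply(anns, function(a)
      paste(strsplit(a, "")[[1]][keep], collapse = ""))
  alignment(aln$ids, seqs, column_annotations = anns)
}

#' Hide columns where the query has a gap
#'
#' Removes every column in which the query sequence carries a gap, i.e. hides
#' segments inserted in the homologs relative to the query, so that the
#' remaining columns correspond one-to-one to query residues.
#'
#' @param aln An [alignment()].
#' @param query_id Identifier of the query sequence.
#' @return A list with elements `alignment` (the masked alignment) and `mask`
#'   (a [column_mask()] whose removals are tagged `"query_gap"`).
#' @export
#' @examples
#' aln <- alignment(c("q", "h"), c("AC-G", "ACDG"))
#' mask_query_insertions(aln, "q")$alignment$length  # 3
mask_query_insertions <- function(aln, query_id) {
  stopifnot(inherits(aln, "alignment"))
  if (!query_id %in% aln$ids)
    stop("unknown query id: ", query_id)
  qchars <- strsplit(aln$seqs[aln$ids == query_id], "")[[1]]
  keep <- which(qchars != "-")
  drop <- which(qchars == "-")
  removed <- rep("query_gap", length(drop))
  names(removed) <- drop
  list(alignment = subset_columns(aln, keep),
       mask = column_mask(keep, removed))
}

#' Gap fraction of an alignment column
#'
#' Fraction of sequences carrying `-` at column `l`. Ambiguity codes count
#' as residues, not gaps.
#'
#' @param aln An [alignment()].
#' @param l 1-based column index.
#' @return A fraction in `[0, 1]`.
#' @export
column_gap_fraction <- function(aln, l) {
  stopifnot(inherits(aln, "alignment"))
  l <- as.integer(l)
  if (any(l < 1L) || any(l > aln$length))
    stop("column index out of range [1, ", aln$length, "]")
  m <- aln_matrix(aln)
  colMeans(m[, l, drop = FALSE] == "-")
}

#' Per-column conservation score (0-10)
#'
#' If the alignment carries an explicit per-column conservation annotation
#' (a `#=GC` tag whose name contains "cons"), the annotated digit is
#' returned verbatim (`0`-`9`; `*` reads as 10). Otherwise the score is
#' `floor(10 * p)` where `p` is the proportion of the single most frequent
#' non-gap residue among non-gap entries (ambiguity codes count in the
#' denominator but cannot be the modal residue). An all-gap column scores 0.
#'
#' @param aln An [alignment()].
#' @param l 1-based column index (vectorised).
#' @return Integer score(s) in 0..10.
#' @export
conservation_score <- function(aln, l) {
  stopifnot(inherits(aln, "alignment"))
  l <- as.integer(l)
  if (any(l < 1L) || any(l > aln$length))
    stop("column index out of range [1, ", aln$length, "]")
  ann <- NULL
  if (!is.null(aln$column_annotations)) {
    tag <- grep("cons", names(aln$column_annotations),
                ignore.case = TRUE, value = TRUE)
    if (length(tag) > 0L)
      ann <- strsplit(aln$column_annotations[[tag[1L]]], "")[[1]]
  }
  m <- aln_matrix(aln)
  vapply(l, function(j) {
    if (!is.null(ann)) {
      ch <- ann[j]
      if (ch %in% as.character(0:9)) return(as.integer(ch))
      if (ch == "*") return(10L)
    }
    col <- m[, j]
    nongap <- col[col != "-"]
    if (length(nongap) == 0L) return(0L)
    standard <- nongap[!nongap %in% c("X", "B", "Z", "U", "O")]
    if (length(standard) == 0L) return(0L)
    as.integer(floor(10 * max(table(standard)) / length(nongap)))
  }, integer(1))
}

#' Filter alignment columns by gap fraction and conservation
#'
#' Keeps column `l` iff `column_gap_fraction(aln, l) < max_gap` **and**
#' `conservation_score(aln, l) > min_cons`. Both inequalities are strict: a
#' column at exactly 30 % gaps or score exactly 8 is removed.
#'
#' @param aln An [alignment()].
#' @param max_gap Maximum tolerated gap fraction (default 0.30).
#' @param min_cons Conservation score that must be exceeded (default 8).
#' @return A list with elements `alignment` and `mask` (a [column_mask()];
#'   removals are tagged `"gap_fraction"` or `"low_conservation"`, with the
#'   gap test applied first).
#' @export
filter_columns <- function(aln, max_gap = 0.30, min_cons = 8) {
  stopifnot(inherits(aln, "alignment"), max_gap >= 0, max_gap <= 1)
  if (aln$length == 0L)
    return(list(alignment = aln, mask = column_mask(integer(0))))
  gf <- column_gap_fraction(aln, seq_len(aln$length))
  cs <- conservation_score(aln, seq_len(aln$length))
  keep <- gf < max_gap & cs > min_cons
  reason <- ifelse(gf >= max_gap, "gap_fraction", "low_conservation")
  removed <- reason[!keep]
  names(removed) <- which(!keep)
  list(alignment = subset_columns(aln, which(keep)),
       mask = column_mask(which(keep), removed))
}
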
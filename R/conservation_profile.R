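#' Per-column residue frequencies, gap fraction and information content
#'
#' Residue frequencies use the total number of sequences as denominator
#' (gaps tallied separately), so frequencies plus the gap fraction sum to
#' one per column. Information content is `log2(20)` minus the Shannon
#' entropy of the column's non-gap residue distribution, in bits.
#'
#' @param alignment named character vector of gapped rows (see
#'   [read_alignment()]), a data.frame with `id`/`sequence`, or a character
#'   matrix.
#' @return An object of class `column_profile`: list with `freq` (residues
#'   x columns matrix, denominator = number of sequences), `gap_fraction`,
#'   and `ic` (bits) per column.
#' @export
column_profile <- function(alignment) {
  m <- as_alignment_matrix(alignment)
  n <- nrow(m)
  if (n == 0 || ncol(m) == 0) stop("empty alignment")
  letters_all <- c(AA_STANDARD, AA_EXTRA)
  freq <- apply(m, 2, function(col) {
    table(factor(col, levels = letters_all)) / n
  })
  rownames(freq) <- letters_all
  gap_fraction <- apply(m, 2, function(col) mean(col %in% c("-", ".")))
  ic <- vapply(seq_len(ncol(m)), function(j) {
    column_ic(m[, j])
  }, numeric(1))
  structure(list(freq = freq, gap_fraction = gap_fraction, ic = ic,
                 n_sequences = n, width = ncol(m)),
            class = "column_profile")
}

# IC (bits) of one alignment column from its non-gap standard-residue
# distribution; all-gap columns get 0 by convention.
column_ic <- function(col, small_sample_correction = FALSE) {
  res <- col[col %in% AA_STANDARD]
  if (length(res) == 0) return(0)
  p <- table(res) / length(res)
  h <- -sum(p * log2(p))
  ic <- log2(20) - h
  if (small_sample_correction) {
    ic <- ic - (length(AA_STANDARD) - 1) / (2 * log(2) * length(res))
  }
  max(ic, 0)
}

#' @export
print.column_profile <- function(x, ...) {
  cat("<column_profile> ", x$n_sequences, " sequences x ", x$width,
      " columns; mean IC ", sprintf("%.2f", mean(x$ic)), " bits\n", sep = "")
  invisible(x)
}

#' Conservation report for mapped key residues
#'
#' Reports, for each labelled domain position mapped to an alignment
#' column, the percentage of sequences bearing each expected residue at
#' that column (rounded to whole percent). Dual expectations such as `"IV"`
#' produce one row per residue.
#'
#' @param alignment see [column_profile()].
#' @param position_map named integer vector, label -> alignment column,
#'   e.g. `c(K2 = 4, K3 = 5, R5 = 7, IV47 = 57, Q50 = 60, N51 = 61, R55 = 65)`.
#' @param expected_residues named character vector, label -> expected
#'   residue letters (several letters = several rows), e.g.
#'   `c(K2 = "K", ..., IV47 = "IV")`. Defaults to the letters in each label.
#' @param denominator `"all"` (gaps count against conservation; default) or
#'   `"nongap"` (percent of non-gap rows only).
#' @return data.frame with columns `label`, `column`, `residue`, `count`,
#'   `percent`.
#' @export
key_residue_report <- function(alignment, position_map,
                               expected_residues = NULL,
                               denominator = c("all", "nongap")) {
  denominator <- match.arg(denominator)
  m <- as_alignment_matrix(alignment)
  if (is.null(names(position_map)) || any(!nzchar(names(position_map)))) {
    stop("position_map must be a named vector (label -> column)")
  }
  cols <- as.integer(position_map)
  if (any(cols < 1 | cols > ncol(m))) {
    stop("mapped column(s) outside alignment width (", ncol(m), "): ",
         paste(names(position_map)[cols < 1 | cols > ncol(m)], collapse = ", "))
  }
  if (is.unsorted(cols, strictly = TRUE)) {
    stop("mapped columns must be strictly increasing")
  }
  if (is.null(expected_residues)) {
    expected_residues <- setNames(gsub("[^A-Z]", "", names(position_map)),
                                  names(position_map))
  }
  rows <- list()
  for (label in names(position_map)) {
    col <- m[, position_map[[label]]]
    n <- if (denominator == "all") length(col) else sum(col %in% AA_STANDARD)
    for (res in strsplit(expected_residues[[label]], "")[[1]]) {
      cnt <- sum(col == res)
      rows[[length(rows) + 1]] <- data.frame(
        label = label, column = as.integer(position_map[[label]]),
        residue = res, count = cnt,
        percent = if (n > 0) round(100 * cnt / n) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Position frequency matrix and information content for logo rendering
#'
#' PFM columns are normalized over non-gap standard residues and sum to 1;
#' IC per column is `log2(20)` minus the Shannon entropy of that
#' distribution, optionally with the small-sample correction
#' `(19) / (2 ln 2 n)` (useful for small synthetic sets; negligible for
#' family-sized alignments). All-gap columns get IC 0 and are flagged.
#'
#' @param alignment see [column_profile()]; at least 2 rows.
#' @param small_sample_correction apply the correction (default `FALSE`).
#' @return List with `pfm` (20 x width matrix), `ic` (bits), and
#'   `all_gap_columns` (integer vector of flagged columns).
#' @export
region_logo <- function(alignment, small_sample_correction = FALSE) {
  m <- as_alignment_matrix(alignment)
  if (nrow(m) < 2) stop("a logo needs at least 2 aligned sequences")
  pfm <- apply(m, 2, function(col) {
    res <- col[col %in% AA_STANDARD]
    if (length(res) == 0) return(setNames(rep(0, 20), AA_STANDARD))
    table(factor(res, levels = AA_STANDARD)) / length(res)
  })
  pfm <- matrix(as.numeric(pfm), nrow = 20,
                dimnames = list(AA_STANDARD, paste0("col", seq_len(ncol(m)))))
  ic <- vapply(seq_len(ncol(m)), function(j) {
    column_ic(m[, j], small_sample_correction = small_sample_correction)
  }, numeric(1))
  all_gap <- which(colSums(pfm) == 0)
  if (length(all_gap) > 0) {
    warning("all-gap column(s): ", paste(all_gap, collapse = ", "),
            "; IC set to 0")
  }
  list(pfm = pfm, ic = ic, all_gap_columns = all_gap)
}
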
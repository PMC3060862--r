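#' Positional residue-composition histogram over relative-position bins
#'
#' Each region is divided into `k` relative-position bins: the residue at
#' 1-based position `i` of a region of length `L` falls in bin
#' `ceiling(i * k / L)`, so the last residue of every region is always in
#' bin `k` (the "last tenth" for the default `k = 10`). Counts are pooled
#' across all regions (residue-weighted); per-protein averaging is
#' available via `per_protein = TRUE`.
#'
#' Non-standard residues (B, Z, U, X) are tallied but excluded from bin
#' totals unless `count_nonstandard = TRUE`.
#'
#' @param regions character vector of region sequences (empty ones are
#'   skipped).
#' @param residue focal one-letter residue, e.g. `"W"` for tryptophan.
#' @param k number of bins (default 10 — deciles).
#' @param per_protein average per-protein frequencies instead of pooling.
#' @param count_nonstandard include B/Z/U/X in bin totals.
#' @return An object of class `frequency_profile` with the per-bin count
#'   matrix, totals, focal-residue frequencies, and advisory binomial
#'   enrichment p-values of each bin against the pooled background.
#' @export
decile_histogram <- function(regions, residue, k = 10L, per_protein = FALSE,
                             count_nonstandard = FALSE) {
  if (k < 1) stop("k must be >= 1")
  if (!is.character(residue) || nchar(residue) != 1) {
    stop("residue must be a single one-letter code")
  }
  residue <- toupper(residue)
  regions <- regions[nchar(regions) > 0]
  if (length(regions) == 0) stop("all regions are empty")
  letters_all <- c(AA_STANDARD, AA_EXTRA)
  counts <- matrix(0, nrow = length(letters_all), ncol = k,
                   dimnames = list(letters_all, paste0("bin", seq_len(k))))
  per_protein_freq <- matrix(NA_real_, nrow = length(regions), ncol = k)
  for (r in seq_along(regions)) {
    chars <- strsplit(toupper(regions[[r]]), "")[[1]]
    L <- length(chars)
    bins <- ceiling(seq_len(L) * k / L)
    keep <- chars %in% letters_all
    tab <- table(factor(chars[keep], levels = letters_all),
                 factor(bins[keep], levels = seq_len(k)))
    counts <- counts + unclass(tab)
    denom_r <- colSums(tab[AA_STANDARD, , drop = FALSE])
    if (count_nonstandard) denom_r <- colSums(tab)
    foc_r <- if (residue %in% letters_all) tab[residue, ] else rep(0, k)
    per_protein_freq[r, ] <- ifelse(denom_r > 0, foc_r / denom_r, NA_real_)
  }
  denom_rows <- if (count_nonstandard) letters_all else AA_STANDARD
  totals <- colSums(counts[denom_rows, , drop = FALSE])
  focal_counts <- if (residue %in% letters_all) counts[residue, ] else rep(0, k)
  frequency <- ifelse(totals > 0, focal_counts / totals, NA_real_)
  if (per_protein) {
    frequency <- colMeans(per_protein_freq, na.rm = TRUE)
  }
  background <- sum(focal_counts) / sum(totals)
  p_enrich <- vapply(seq_len(k), function(b) {
    if (totals[b] == 0) return(NA_real_)
    stats::pbinom(focal_counts[b] - 1, totals[b], background,
                  lower.tail = FALSE)
  }, numeric(1))
  structure(list(
    k = as.integer(k), residue = residue, n_regions = length(regions),
    counts = counts, totals = totals, focal_counts = focal_counts,
    frequency = frequency, background_frequency = background,
    pooled = !per_protein, p_enrichment = p_enrich
  ), class = "frequency_profile")
}

#' @export
print.frequency_profile <- function(x, ...) {
  cat("<frequency_profile> residue ", x$residue, ", ", x$k, " bins, ",
      x$n_regions, " regions (", if (x$pooled) "pooled" else "per-protein",
      ")\n", sep = "")
  print(round(setNames(x$frequency, paste0("bin", seq_len(x$k))), 4))
  invisible(x)
}

#' @export
as.data.frame.frequency_profile <- function(x, ...) {
  data.frame(bin = seq_len(x$k), total = as.integer(x$totals),
             focal_count = as.integer(x$focal_counts),
             frequency = as.numeric(x$frequency),
             p_enrichment = x$p_enrichment)
}

#' Bar plot of a positional frequency profile
#'
#' @param profile a `frequency_profile`.
#' @return A ggplot object.
#' @export
plot_decile_profile <- function(profile) {
  df <- as.data.frame(profile)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(bin), y = frequency)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_hline(yintercept = profile$background_frequency,
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "relative-position bin",
                  y = paste0("frequency of ", profile$residue),
                  title = paste0(profile$residue, " positional frequency (",
                                 profile$n_regions, " regions)")) +
    ggplot2::theme_minimal()
}
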
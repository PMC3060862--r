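#' Compile a PROSITE-style degenerate amino-acid pattern
#'
#' Pattern elements are separated by `-`: a single residue letter, `x` for
#' any residue, `[...]` for an allowed set, `{...}` for an excluded set
#' (complement within the 20 standard amino acids). The sumoylation
#' consensus Psi-K-x-E/D, with Psi a large hydrophobic residue, is written
#' `"[FVIML]-K-x-[ED]"`; its control, identical except that the last
#' position must *not* be acidic, is `"[FVIML]-K-x-{ED}"`.
#'
#' Constrained positions never match ambiguity codes (B, Z, U, X); an
#' unconstrained `x` matches any residue.
#'
#' @param source pattern string.
#' @return An object of class `consensus_pattern` with elements `source`,
#'   `positions` (list of allowed-residue character vectors), `length`, and
#'   `regex` (a perl regex over one window).
#' @export
compile_pattern <- function(source) {
  if (!is.character(source) || length(source) != 1 || !nzchar(source)) {
    stop("pattern source must be a single non-empty string")
  }
  elements <- strsplit(source, "-", fixed = TRUE)[[1]]
  if (any(!nzchar(elements))) {
    stop("empty pattern element (stray '-') in \"", source, "\"")
  }
  positions <- vector("list", length(elements))
  for (i in seq_along(elements)) {
    el <- elements[i]
    if (el == "x") {
      positions[[i]] <- AA_STANDARD
      attr(positions[[i]], "any") <- TRUE
    } else if (grepl("^\\[[A-Z]+\\]$", el)) {
      positions[[i]] <- unique(strsplit(substr(el, 2, nchar(el) - 1), "")[[1]])
    } else if (grepl("^\\{[A-Z]+\\}$", el)) {
      excluded <- strsplit(substr(el, 2, nchar(el) - 1), "")[[1]]
      allowed <- setdiff(AA_STANDARD, excluded)
      if (length(allowed) == 0) {
        stop("pattern element ", i, " (\"", el, "\") excludes every residue")
      }
      positions[[i]] <- allowed
    } else if (grepl("^[A-Z]$", el)) {
      positions[[i]] <- el
    } else if (el %in% c("[]", "{}")) {
      stop("empty bracket set at pattern element ", i, " in \"", source, "\"")
    } else {
      stop("cannot parse pattern element ", i, " (\"", el, "\") in \"",
           source, "\"")
    }
    bad <- setdiff(positions[[i]], AA_STANDARD)
    if (length(bad) > 0) {
      stop("non-standard residue(s) ", paste(bad, collapse = ""),
           " at pattern element ", i, " in \"", source, "\"")
    }
  }
  regex <- paste0(vapply(positions, function(p) {
    if (isTRUE(attr(p, "any"))) "." else paste0("[", paste(p, collapse = ""), "]")
  }, character(1)), collapse = "")
  structure(
    list(source = source, positions = positions,
         length = length(positions), regex = regex),
    class = "consensus_pattern"
  )
}

#' @export
print.consensus_pattern <- function(x, ...) {
  cat("<consensus_pattern> ", x$source, " (", x$length, " positions)\n",
      sep = "")
  invisible(x)
}

#' Render a compiled pattern back to its source string
#'
#' @param pattern a `consensus_pattern`.
#' @return The PROSITE-style source string.
#' @export
render_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "consensus_pattern"))
  pattern$source
}

as_pattern <- function(pattern) {
  if (inherits(pattern, "consensus_pattern")) pattern else compile_pattern(pattern)
}

#' Scan one sequence for all (overlapping) pattern matches
#'
#' Every start offset is tested and overlapping matches are all reported,
#' in ascending start order. Coordinates are 1-based inclusive relative to
#' the scanned sequence.
#'
#' @param sequence an amino-acid string.
#' @param pattern a `consensus_pattern` or pattern source string.
#' @return data.frame with columns `start`, `end`, `matched_seq`.
#' @export
scan_sequence <- function(sequence, pattern) {
  pattern <- as_pattern(pattern)
  empty <- data.frame(start = integer(), end = integer(),
                      matched_seq = character(), stringsAsFactors = FALSE)
  if (nchar(sequence) < pattern$length) return(empty)
  m <- gregexpr(paste0("(?=", pattern$regex, ")"), sequence, perl = TRUE)[[1]]
  starts <- as.integer(m)
  if (length(starts) == 0 || starts[1] == -1) return(empty)
  ends <- starts + pattern$length - 1L
  data.frame(start = starts, end = ends,
             matched_seq = substring(sequence, starts, ends),
             stringsAsFactors = FALSE)
}

#' Scan a set of region sequences
#'
#' @param sequences named character vector (names = protein ids), e.g. from
#'   [region_sequences()].
#' @param pattern a `consensus_pattern` or pattern source string.
#' @param motif_id label written into the `motif_id` column (defaults to the
#'   pattern source).
#' @return data.frame in the `motifs` schema (`protein_id`, `motif_id`,
#'   `start`, `end`, `matched_seq`), coordinates relative to the scanned
#'   sequences.
#' @export
scan_sequences <- function(sequences, pattern, motif_id = NULL) {
  pattern <- as_pattern(pattern)
  motif_id <- motif_id %||% pattern$source
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("sequences must be a named character vector")
  }
  hits <- lapply(names(sequences), function(id) {
    h <- scan_sequence(sequences[[id]], pattern)
    if (nrow(h) == 0) return(NULL)
    cbind(data.frame(protein_id = id, motif_id = motif_id,
                     stringsAsFactors = FALSE), h)
  })
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(protein_id = character(), motif_id = character(),
                      start = integer(), end = integer(),
                      matched_seq = character(), stringsAsFactors = FALSE)
  }
  out
}

#' Canonical-versus-control enrichment summary for a pattern scan
#'
#' Scans every region sequence with a canonical pattern and a control
#' pattern, tallies occurrences and proteins with at least one hit, builds
#' per-position residue-identity distributions of the canonical matches,
#' and reports the occurrence-count ratio canonical/control. The ratio is
#' occurrence-based (143/82 style), not protein-based; a zero control count
#' makes the ratio `NA` with a warning, never infinity.
#'
#' @param sequences named character vector of region sequences.
#' @param canonical canonical pattern (string or `consensus_pattern`).
#' @param control control pattern.
#' @return An object of class `enrichment_result`.
#' @export
enrichment_summary <- function(sequences, canonical, control) {
  if (length(sequences) < 1) stop("at least one region sequence is required")
  canonical <- as_pattern(canonical)
  control <- as_pattern(control)
  can_hits <- scan_sequences(sequences, canonical)
  ctl_hits <- scan_sequences(sequences, control)
  position_counts <- lapply(seq_len(canonical$length), function(i) {
    if (nrow(can_hits) == 0) return(table(factor(character(), AA_STANDARD)))
    res <- substr(can_hits$matched_seq, i, i)
    table(factor(res, levels = union(AA_STANDARD, unique(res))))
  })
  position_percent <- lapply(position_counts, function(tab) {
    n <- sum(tab)
    if (n == 0) return(tab * NA_real_)
    round(100 * tab / n)
  })
  ratio <- if (nrow(ctl_hits) == 0) {
    warning("control pattern has zero occurrences; ratio undefined")
    NA_real_
  } else {
    nrow(can_hits) / nrow(ctl_hits)
  }
  structure(list(
    pattern = canonical$source,
    control_pattern = control$source,
    n_sequences = length(sequences),
    n_occurrences = nrow(can_hits),
    n_proteins_with_hit = length(unique(can_hits$protein_id)),
    n_control_occurrences = nrow(ctl_hits),
    n_control_proteins = length(unique(ctl_hits$protein_id)),
    ratio = ratio,
    position_counts = position_counts,
    position_percent = position_percent,
    occurrences = can_hits,
    control_occurrences = ctl_hits
  ), class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> ", x$pattern, " vs ", x$control_pattern, "\n",
      "  canonical: ", x$n_occurrences, " occurrence(s) in ",
      x$n_proteins_with_hit, " of ", x$n_sequences, " proteins\n",
      "  control:   ", x$n_control_occurrences, " occurrence(s) in ",
      x$n_control_proteins, " proteins\n",
      "  canonical/control ratio: ",
      if (is.na(x$ratio)) "undefined" else sprintf("%.2f", x$ratio), "\n",
      sep = "")
  invisible(x)
}

#' Count occurrences per protein, e.g. how many proteins carry exactly one,
#' two, ... sites
#'
#' @param occurrences data.frame in the `motifs` schema.
#' @return table of per-protein occurrence counts.
#' @export
occurrence_tally <- function(occurrences) {
  table(table(occurrences$protein_id))
}
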
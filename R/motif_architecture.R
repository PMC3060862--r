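#' Assign motif occurrences to regions and proximal/distal CTR zones
#'
#' Each occurrence (whole-protein coordinates) is assigned to the region —
#' NTR, core or CTR — containing its midpoint `(start + end) / 2`
#' (half-integer midpoints are rounded up); occurrences whose start and end
#' fall in different regions are flagged rather than split. For CTR
#' occurrences the relative midpoint `((start+end)/2 - ctr_start + 0.5) /
#' ctr_length` places the occurrence in the proximal zone (adjacent to the
#' HALZ) when it is below the boundary fraction `b`, else in the distal
#' zone (towards the protein terminus).
#'
#' @param occurrences data.frame in the `motifs` schema, whole-protein
#'   coordinates.
#' @param partitions data.frame from [partition_family()].
#' @param boundary proximal/distal boundary fraction `b` (default 0.5).
#' @return data.frame: the occurrences plus `region`, `region_start`,
#'   `region_end` (region-relative coordinates), `relative_position`
#'   (midpoint / region length, in \[0,1\]), `ctr_zone` (`"proximal"`,
#'   `"distal"` or `NA`), and `spans_boundary`.
#' @export
localize_occurrences <- function(occurrences, partitions, boundary = 0.5) {
  if (boundary <= 0 || boundary >= 1) stop("boundary must be in (0, 1)")
  idx <- match(occurrences$protein_id, partitions$protein_id)
  if (anyNA(idx)) {
    stop("occurrence(s) for protein(s) without a partition: ",
         paste(unique(occurrences$protein_id[is.na(idx)]), collapse = ", "))
  }
  p <- partitions[idx, , drop = FALSE]
  mid <- (occurrences$start + occurrences$end) / 2
  mid_res <- ceiling(mid)  # residue holding the midpoint (round half up)
  region <- ifelse(!is.na(p$ntr_end) & mid_res <= p$ntr_end, "NTR",
            ifelse(mid_res <= p$core_end, "core", "CTR"))
  reg_start <- ifelse(region == "NTR", 1L,
               ifelse(region == "core", p$core_start, p$ctr_start))
  reg_end <- ifelse(region == "NTR", p$ntr_end,
             ifelse(region == "core", p$core_end, p$ctr_end))
  reg_len <- reg_end - reg_start + 1L
  rel <- (mid - reg_start + 0.5) / reg_len
  region_of <- function(pos) {
    ifelse(!is.na(p$ntr_end) & pos <= p$ntr_end, "NTR",
           ifelse(pos <= p$core_end, "core", "CTR"))
  }
  spans <- region_of(occurrences$start) != region_of(occurrences$end)
  if (any(spans)) {
    warning(sum(spans), " occurrence(s) span a region boundary; ",
            "assigned by midpoint and flagged")
  }
  out <- occurrences
  out$region <- region
  out$region_start <- as.integer(occurrences$start - reg_start + 1L)
  out$region_end <- as.integer(occurrences$end - reg_start + 1L)
  out$relative_position <- pmin(pmax(rel, 0), 1)
  out$ctr_zone <- ifelse(region == "CTR",
                         ifelse(rel < boundary, "proximal", "distal"),
                         NA_character_)
  out$spans_boundary <- spans
  out
}

#' Motif-by-group specificity matrix
#'
#' For every motif and group: the fraction of the group's members carrying
#' at least one occurrence (`member_fraction`), and the fraction of the
#' motif's occurrences falling in the group (`occurrence_fraction`, sums to
#' 1 per motif). A motif present in at least `presence` of exactly one
#' group's members and below `absence` in every other group is flagged
#' group-characteristic.
#'
#' @param occurrences data.frame with `protein_id` and `motif_id` (e.g.
#'   from [localize_occurrences()]).
#' @param groups data.frame in the `groups` schema covering all proteins of
#'   the family (members without occurrences included); proteins missing a
#'   label are placed in `"unassigned"`.
#' @param presence presence threshold in the characteristic group (0.5).
#' @param absence absence threshold in all other groups (0.1).
#' @return An object of class `specificity_matrix`: list with
#'   `member_fraction` and `occurrence_fraction` (motif x group matrices),
#'   `group_sizes`, and `characteristic` (named character vector, motif ->
#'   group or `NA`).
#' @export
group_specificity <- function(occurrences, groups, presence = 0.5,
                              absence = 0.1) {
  groups <- groups[!duplicated(groups$protein_id), , drop = FALSE]
  groups$group[is.na(groups$group) | !nzchar(groups$group)] <- "unassigned"
  missing_label <- setdiff(unique(occurrences$protein_id), groups$protein_id)
  if (length(missing_label) > 0) {
    groups <- rbind(groups[, c("protein_id", "group")],
                    data.frame(protein_id = missing_label,
                               group = "unassigned",
                               stringsAsFactors = FALSE))
  }
  group_levels <- sort(unique(groups$group))
  motif_levels <- sort(unique(occurrences$motif_id))
  group_sizes <- table(factor(groups$group, levels = group_levels))
  if (any(group_sizes == 0)) {
    warning("empty group(s): ",
            paste(group_levels[group_sizes == 0], collapse = ", "))
  }
  occ_group <- groups$group[match(occurrences$protein_id, groups$protein_id)]
  occurrence_counts <- table(factor(occurrences$motif_id, motif_levels),
                             factor(occ_group, group_levels))
  occurrence_fraction <- occurrence_counts / pmax(rowSums(occurrence_counts), 1)
  carriers <- unique(occurrences[, c("protein_id", "motif_id")])
  carrier_group <- groups$group[match(carriers$protein_id, groups$protein_id)]
  carrier_counts <- table(factor(carriers$motif_id, motif_levels),
                          factor(carrier_group, group_levels))
  member_fraction <- sweep(carrier_counts, 2,
                           pmax(as.numeric(group_sizes), 1), "/")
  characteristic <- vapply(motif_levels, function(m) {
    mf <- member_fraction[m, ]
    hit <- names(mf)[mf >= presence]
    if (length(hit) == 1 && all(mf[setdiff(names(mf), hit)] < absence)) {
      hit
    } else NA_character_
  }, character(1))
  structure(list(
    member_fraction = unclass(member_fraction),
    occurrence_fraction = unclass(occurrence_fraction),
    group_sizes = group_sizes,
    characteristic = characteristic,
    presence_threshold = presence, absence_threshold = absence
  ), class = "specificity_matrix")
}

#' @export
print.specificity_matrix <- function(x, ...) {
  cat("<specificity_matrix> ", nrow(x$member_fraction), " motif(s) x ",
      ncol(x$member_fraction), " group(s)\n", sep = "")
  chr <- x$characteristic[!is.na(x$characteristic)]
  if (length(chr) > 0) {
    cat("  group-characteristic (>=", x$presence_threshold * 100,
        "% of one group, <", x$absence_threshold * 100, "% elsewhere):\n",
        sep = "")
    for (m in names(chr)) cat("    ", m, " -> group ", chr[[m]], "\n", sep = "")
  } else {
    cat("  no group-characteristic motif\n")
  }
  invisible(x)
}

AA_AROMATIC <- c("W", "F", "Y")
AA_LARGE_HYDROPHOBIC <- c("W", "F", "Y", "L", "I", "V", "M")
AA_ACIDIC <- c("D", "E")
AA_BASIC <- c("K", "R")

#' AHA-likeness features of a motif or terminal-region set
#'
#' Activation motifs of the AHA type (Aromatic, large Hydrophobic, Acidic
#' context), as described for heat-stress transcription factors, pair
#' aromatic/large-hydrophobic core positions with an acidic sequence
#' context. Given a set of matched sequences (equal length, e.g. a motif's
#' occurrences) or terminal windows, this computes per-position aromatic
#' and large-hydrophobic frequencies, the overall acidic fraction, and
#' terminal-window tryptophan statistics.
#'
#' Flags: `aromatic_core` — some position has aromatic frequency >=
#' `tau_arom`; `acidic_context` — the pooled D/E fraction >=
#' `tau_acidic`; `basic_adjacent` — in a majority of sequences a K/R lies
#' within one residue of a tryptophan of the terminal window (the atypical
#' configuration seen in HAHB4's C-terminus).
#'
#' @param sequences character vector of amino-acid strings. Per-position
#'   frequencies are computed when all sequences have equal length,
#'   otherwise only pooled statistics are returned.
#' @param tau_arom aromatic-core frequency threshold (default 0.5).
#' @param tau_acidic acidic-context fraction threshold (default 0.25).
#' @param terminal_window number of C-terminal residues inspected for
#'   tryptophans (default 10).
#' @return An object of class `aha_report`.
#' @export
aha_features <- function(sequences, tau_arom = 0.5, tau_acidic = 0.25,
                         terminal_window = 10L) {
  sequences <- toupper(sequences[nchar(sequences) > 0])
  if (length(sequences) == 0) stop("aha_features needs at least one sequence")
  chars <- strsplit(sequences, "")
  equal_len <- length(unique(lengths(chars))) == 1
  if (equal_len) {
    m <- do.call(rbind, chars)
    aromatic_freq <- colMeans(matrix(m %in% AA_AROMATIC, nrow = nrow(m)))
    hydrophobic_freq <- colMeans(matrix(m %in% AA_LARGE_HYDROPHOBIC,
                                        nrow = nrow(m)))
  } else {
    aromatic_freq <- hydrophobic_freq <- NULL
  }
  all_chars <- unlist(chars)
  acidic_fraction <- mean(all_chars %in% AA_ACIDIC)
  term_w <- function(s) {
    tail_chars <- strsplit(substr(s, max(1, nchar(s) - terminal_window + 1),
                                  nchar(s)), "")[[1]]
    which(tail_chars == "W") + max(1, nchar(s) - terminal_window + 1) - 1
  }
  w_positions <- lapply(sequences, term_w)
  terminal_trp_counts <- lengths(w_positions)
  basic_near_w <- vapply(seq_along(sequences), function(i) {
    ws <- w_positions[[i]]
    if (length(ws) == 0) return(FALSE)
    ch <- chars[[i]]
    any(vapply(ws, function(w) {
      nb <- ch[max(1, w - 1):min(length(ch), w + 1)]
      any(nb %in% AA_BASIC)
    }, logical(1)))
  }, logical(1))
  flags <- c(
    aromatic_core = equal_len && any(aromatic_freq >= tau_arom),
    acidic_context = acidic_fraction >= tau_acidic,
    basic_adjacent = mean(basic_near_w) > 0.5
  )
  structure(list(
    n_sequences = length(sequences),
    aromatic_freq = aromatic_freq, hydrophobic_freq = hydrophobic_freq,
    acidic_fraction = acidic_fraction,
    terminal_window = as.integer(terminal_window),
    terminal_trp_counts = terminal_trp_counts,
    mean_terminal_trp = mean(terminal_trp_counts),
    flags = flags,
    params = c(tau_arom = tau_arom, tau_acidic = tau_acidic)
  ), class = "aha_report")
}

#' @export
print.aha_report <- function(x, ...) {
  cat("<aha_report> ", x$n_sequences, " sequence(s); acidic fraction ",
      sprintf("%.2f", x$acidic_fraction), "; mean terminal Trp ",
      sprintf("%.2f", x$mean_terminal_trp), "\n  flags: ",
      paste(names(x$flags)[x$flags], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Overlap of predicted modification sites with motifs and regions
#'
#' Filters site predictions at the given score cutoffs (phosphorylation
#' 0.9, NLS 0.6 by default), then counts retained sites inside each motif's
#' occurrences and inside each region, and assigns each NLS interval to the
#' region holding its midpoint.
#'
#' @param partitions data.frame from [partition_family()].
#' @param sites data.frame in the `sites` schema (whole-protein
#'   coordinates).
#' @param annotations optional data.frame from [localize_occurrences()]
#'   (whole-protein coordinates); motif overlap counts are computed when
#'   supplied.
#' @param cutoffs named numeric vector of score cutoffs per prediction kind.
#' @return List with `by_region` (kind x region count table), `by_motif`
#'   (per-motif retained-site counts, when `annotations` given),
#'   `nls_regions` (per NLS interval, its host region), and
#'   `retained_sites`.
#' @export
overlay_sites <- function(partitions, sites, annotations = NULL,
                          cutoffs = c(phospho = 0.9, nls = 0.6)) {
  unknown_kind <- setdiff(unique(sites$kind), names(cutoffs))
  if (length(unknown_kind) > 0) {
    stop("no cutoff for prediction kind(s): ",
         paste(unknown_kind, collapse = ", "))
  }
  keep <- sites$score >= cutoffs[sites$kind]
  retained <- sites[keep, , drop = FALSE]
  regions <- c("NTR", "core", "CTR")
  if (nrow(retained) > 0) {
    idx <- match(retained$protein_id, partitions$protein_id)
    if (anyNA(idx)) {
      stop("site(s) for protein(s) without a partition: ",
           paste(unique(retained$protein_id[is.na(idx)]), collapse = ", "))
    }
    p <- partitions[idx, , drop = FALSE]
    hi <- if ("end" %in% names(retained)) {
      ifelse(is.na(retained$end), retained$start, retained$end)
    } else retained$start
    mid <- ceiling((retained$start + hi) / 2)
    site_region <- ifelse(!is.na(p$ntr_end) & mid <= p$ntr_end, "NTR",
                   ifelse(mid <= p$core_end, "core", "CTR"))
  } else {
    site_region <- character(0)
  }
  by_region <- table(factor(retained$kind, levels = names(cutoffs)),
                     factor(site_region, levels = regions))
  by_motif <- NULL
  if (!is.null(annotations)) {
    motif_levels <- sort(unique(annotations$motif_id))
    counts <- setNames(integer(length(motif_levels)), motif_levels)
    if (nrow(retained) > 0 && nrow(annotations) > 0) {
      for (i in seq_len(nrow(retained))) {
        inside <- annotations$protein_id == retained$protein_id[i] &
          annotations$start <= retained$start[i] &
          annotations$end >= retained$start[i]
        for (m in unique(annotations$motif_id[inside])) {
          counts[[m]] <- counts[[m]] + 1L
        }
      }
    }
    by_motif <- counts
  }
  nls <- retained[retained$kind == "nls", , drop = FALSE]
  nls_regions <- if (nrow(nls) > 0) {
    data.frame(protein_id = nls$protein_id, start = nls$start,
               end = if ("end" %in% names(nls)) nls$end else nls$start,
               region = site_region[retained$kind == "nls"],
               stringsAsFactors = FALSE)
  } else {
    data.frame(protein_id = character(), start = integer(), end = integer(),
               region = character(), stringsAsFactors = FALSE)
  }
  list(by_region = by_region, by_motif = by_motif,
       nls_regions = nls_regions, retained_sites = retained,
       cutoffs = cutoffs)
}

#' Architecture plot: motifs as boxes along each protein
#'
#' A compact rendition of the family's motif architecture: one horizontal
#' lane per protein (ordered by a tree leaf order when given), the core
#' domain shaded, motif occurrences as coloured boxes, retained predicted
#' sites as point glyphs.
#'
#' @param annotations data.frame from [localize_occurrences()].
#' @param partitions data.frame from [partition_family()].
#' @param leaf_order optional id order from [read_tree_leaf_order()].
#' @param sites optional retained sites (e.g. `overlay_sites()$retained_sites`).
#' @return A ggplot object.
#' @export
plot_architecture <- function(annotations, partitions, leaf_order = NULL,
                              sites = NULL) {
  ids <- leaf_order %||% partitions$protein_id
  ids <- ids[ids %in% partitions$protein_id]
  p <- partitions[match(ids, partitions$protein_id), , drop = FALSE]
  p$y <- seq_along(ids)
  ann <- annotations[annotations$protein_id %in% ids, , drop = FALSE]
  ann$y <- p$y[match(ann$protein_id, p$protein_id)]
  g <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = p, ggplot2::aes(x = 1, xend = length,
                                                 y = y, yend = y),
                          colour = "grey70") +
    ggplot2::geom_rect(data = p, ggplot2::aes(xmin = core_start,
                                              xmax = core_end,
                                              ymin = y - 0.3, ymax = y + 0.3),
                       fill = "grey85", colour = NA) +
    ggplot2::geom_rect(data = ann, ggplot2::aes(xmin = start, xmax = end,
                                                ymin = y - 0.35,
                                                ymax = y + 0.35,
                                                fill = motif_id)) +
    ggplot2::scale_y_continuous(breaks = p$y, labels = p$protein_id) +
    ggplot2::labs(x = "residue position", y = NULL, fill = "motif") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
  if (!is.null(sites) && nrow(sites) > 0) {
    s <- sites[sites$protein_id %in% ids, , drop = FALSE]
    s$y <- p$y[match(s$protein_id, p$protein_id)]
    g <- g + ggplot2::geom_point(data = s,
                                 ggplot2::aes(x = start, y = y + 0.45,
                                              shape = kind), size = 0.8)
  }
  g
}
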
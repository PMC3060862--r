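#' Partition one protein into NTR, core domain, and CTR
#'
#' The core HD-Zip block spans from the HD hit's start to the end of the
#' HALZ hit (or the HD hit if it extends further): the two profile-HMM
#' models abut or overlap and the family treats them as one block. The NTR
#' is everything before the core, the CTR everything after; either may be
#' empty.
#'
#' @param record one-row data.frame (or list) with `id` and `sequence`.
#' @param hits data.frame in the `domains` schema for this protein.
#' @param require_halz if `TRUE` (default) a missing HALZ hit is an error;
#'   if `FALSE` the core falls back to the HD hit alone with a warning.
#' @return A one-row data.frame with columns `protein_id`, `length`,
#'   `ntr_start`, `ntr_end`, `ntr_length`, `core_start`, `core_end`,
#'   `core_length`, `ctr_start`, `ctr_end`, `ctr_length`. Empty regions have
#'   `NA` bounds and length 0.
#' @export
partition_protein <- function(record, hits, require_halz = TRUE) {
  id <- record$id
  L <- nchar(record$sequence)
  hits <- hits[hits$protein_id == id, , drop = FALSE]
  hd <- hits[hits$domain == "HD", , drop = FALSE]
  halz <- hits[hits$domain == "HALZ", , drop = FALSE]
  if (nrow(hd) == 0) stop("no HD hit for protein ", id)
  if (nrow(hd) > 1) {
    warning("multiple HD hits for protein ", id, "; keeping the best-scoring")
    if (!"score" %in% names(hd) || all(is.na(hd$score))) {
      hd <- hd[1, , drop = FALSE]
    } else {
      hd <- hd[which.max(hd$score), , drop = FALSE]
    }
  }
  if (nrow(halz) > 1) stop("more than one HALZ hit for protein ", id)
  if (any(c(hd$start, hd$end, halz$start, halz$end) > L)) {
    stop("domain hit beyond sequence length for protein ", id)
  }
  if (nrow(halz) == 0) {
    if (require_halz) {
      stop("no HALZ hit for protein ", id,
           " (set require_halz = FALSE to fall back to the HD hit)")
    }
    warning("no HALZ hit for protein ", id, "; core taken as the HD hit only")
    core_end <- hd$end
  } else {
    if (halz$end < hd$start) {
      stop("HALZ hit ends before the HD hit starts for protein ", id)
    }
    core_end <- max(hd$end, halz$end)
  }
  core_start <- hd$start
  ntr_len <- core_start - 1L
  ctr_len <- L - core_end
  data.frame(
    protein_id = id, length = L,
    ntr_start = if (ntr_len > 0) 1L else NA_integer_,
    ntr_end = if (ntr_len > 0) as.integer(ntr_len) else NA_integer_,
    ntr_length = as.integer(ntr_len),
    core_start = as.integer(core_start), core_end = as.integer(core_end),
    core_length = as.integer(core_end - core_start + 1L),
    ctr_start = if (ctr_len > 0) as.integer(core_end + 1L) else NA_integer_,
    ctr_end = if (ctr_len > 0) as.integer(L) else NA_integer_,
    ctr_length = as.integer(ctr_len),
    stringsAsFactors = FALSE
  )
}

#' Partition a whole family
#'
#' @param proteins data.frame from [read_fasta()] (optionally with `group`).
#' @param domains data.frame in the `domains` schema.
#' @param require_halz see [partition_protein()].
#' @param on_error `"stop"` (default) to propagate the first per-protein
#'   error, or `"skip"` to drop failing proteins with a warning.
#' @return data.frame of per-protein partitions (see [partition_protein()]).
#' @export
partition_family <- function(proteins, domains, require_halz = TRUE,
                             on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  validate_coordinates(domains, "domains", proteins)
  rows <- lapply(seq_len(nrow(proteins)), function(i) {
    rec <- proteins[i, , drop = FALSE]
    if (on_error == "stop") {
      partition_protein(rec, domains, require_halz = require_halz)
    } else {
      tryCatch(partition_protein(rec, domains, require_halz = require_halz),
               error = function(e) {
                 warning("skipping protein ", rec$id, ": ",
                         conditionMessage(e), call. = FALSE)
                 NULL
               })
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) stop("no protein could be partitioned")
  if (any(out$ctr_length == 0)) {
    warning("protein(s) with empty CTR excluded from CTR-level statistics: ",
            paste(out$protein_id[out$ctr_length == 0], collapse = ", "))
  }
  out
}

#' Extract the sequences of one region across a family
#'
#' @param proteins data.frame from [read_fasta()].
#' @param partitions data.frame from [partition_family()].
#' @param region `"ntr"`, `"core"`, or `"ctr"`.
#' @param drop_empty drop zero-length regions (default `TRUE`).
#' @return Named character vector of region sequences.
#' @export
region_sequences <- function(proteins, partitions,
                             region = c("ntr", "core", "ctr"),
                             drop_empty = TRUE) {
  region <- match.arg(region)
  idx <- match(partitions$protein_id, proteins$id)
  if (anyNA(idx)) {
    stop("partitions reference unknown protein id(s): ",
         paste(partitions$protein_id[is.na(idx)], collapse = ", "))
  }
  s <- partitions[[paste0(region, "_start")]]
  e <- partitions[[paste0(region, "_end")]]
  seqs <- ifelse(is.na(s), "", substr(proteins$sequence[idx], s, e))
  names(seqs) <- partitions$protein_id
  if (drop_empty) seqs <- seqs[nchar(seqs) > 0]
  seqs
}

#' Write the three per-region FASTA files and a region-length summary
#'
#' @inheritParams region_sequences
#' @param out_dir output directory (created if needed). Writes `ntr.fasta`,
#'   `core.fasta`, `ctr.fasta` and `regions.tsv`.
#' @param comment optional provenance comment for `regions.tsv`.
#' @return `out_dir`, invisibly.
#' @export
write_region_fasta <- function(proteins, partitions, out_dir, comment = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (region in c("ntr", "core", "ctr")) {
    seqs <- region_sequences(proteins, partitions, region)
    write_fasta(seqs, file.path(out_dir, paste0(region, ".fasta")))
  }
  write_table(partitions, file.path(out_dir, "regions.tsv"), comment = comment)
  invisible(out_dir)
}
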
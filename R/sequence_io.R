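#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased and a single terminal stop (`*`) is stripped.
#' Internal gap characters are rejected: the family sets handled here are
#' unaligned sequences; use [read_alignment()] for gapped input.
#'
#' @param path path to a FASTA file.
#' @return A data.frame with columns `id` and `sequence`, one row per entry,
#'   input order preserved. An empty file yields a zero-row data.frame with
#'   a warning.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(data.frame(id = character(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  if (any(grepl("-", seqs, fixed = TRUE))) {
    stop("gap characters found in ", path,
         "; use read_alignment() for aligned FASTA")
  }
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for id(s): ",
         paste(ids[nchar(seqs) == 0], collapse = ", "))
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins data.frame with `id` and `sequence` columns, or a named
#'   character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  if (is.character(proteins)) {
    proteins <- data.frame(id = names(proteins), sequence = unname(proteins),
                           stringsAsFactors = FALSE)
  }
  set <- Biostrings::BStringSet(setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a gapped (aligned) FASTA file
#'
#' @param path path to an aligned FASTA file.
#' @return A named character vector of equal-length gapped rows.
#' @export
read_alignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  rows <- toupper(as.character(set))
  names(rows) <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1L)
  if (length(unique(nchar(rows))) > 1) {
    stop("alignment rows have unequal lengths in ", path)
  }
  rows
}

# Convert an alignment (named character vector or read_fasta data.frame)
# to a character matrix, rows = sequences, columns = alignment columns.
as_alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  if (is.data.frame(alignment)) {
    alignment <- setNames(alignment$sequence, alignment$id)
  }
  if (length(alignment) == 0) stop("empty alignment")
  widths <- nchar(alignment)
  if (length(unique(widths)) > 1) stop("alignment rows have unequal lengths")
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment)
  m
}

# Declared TSV schemas: required columns (in order) and optional ones.
TABLE_SCHEMAS <- list(
  domains = list(required = c("protein_id", "domain", "start", "end"),
                 optional = "score",
                 integer  = c("start", "end"),
                 numeric  = "score"),
  sites   = list(required = c("protein_id", "kind", "start", "score"),
                 optional = c("end", "residue"),
                 integer  = c("start", "end"),
                 numeric  = "score"),
  groups  = list(required = c("protein_id", "group"),
                 optional = character(),
                 integer  = character(),
                 numeric  = character()),
  motifs  = list(required = c("protein_id", "motif_id", "start", "end"),
                 optional = "matched_seq",
                 integer  = c("start", "end"),
                 numeric  = character())
)

#' Read a typed pipeline table (TSV)
#'
#' Reads one of the pipeline's tabular interchange formats and validates it
#' against its schema. Lines starting with `#` are treated as comments.
#' When `proteins` is supplied, every coordinate is checked to lie within
#' `[1, protein length]`.
#'
#' @param path path to a TSV file with a header row.
#' @param schema one of `"domains"`, `"sites"`, `"groups"`, `"motifs"`.
#' @param proteins optional data.frame from [read_fasta()] used for
#'   coordinate validation.
#' @return A data.frame with the schema's columns.
#' @export
read_table <- function(path, schema, proteins = NULL) {
  if (!schema %in% names(TABLE_SCHEMAS)) {
    stop("unknown table schema: ", schema, " (expected one of ",
         paste(names(TABLE_SCHEMAS), collapse = ", "), ")")
  }
  sc <- TABLE_SCHEMAS[[schema]]
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  missing_cols <- setdiff(sc$required, names(df))
  if (length(missing_cols) > 0) {
    stop("table ", path, " lacks required column(s) for schema '", schema,
         "': ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, intersect(c(sc$required, sc$optional), names(df)), drop = FALSE]
  for (col in intersect(sc$integer, names(df))) df[[col]] <- as.integer(df[[col]])
  for (col in intersect(sc$numeric, names(df))) df[[col]] <- as.numeric(df[[col]])
  if (schema == "domains" && !all(df$domain %in% c("HD", "HALZ"))) {
    stop("domain labels must be HD or HALZ; found: ",
         paste(setdiff(unique(df$domain), c("HD", "HALZ")), collapse = ", "))
  }
  validate_coordinates(df, schema, proteins, path)
  df
}

validate_coordinates <- function(df, schema, proteins, path = "<table>") {
  coord_cols <- intersect(c("start", "end"), names(df))
  if (length(coord_cols) == 0 || nrow(df) == 0) return(invisible(df))
  for (col in coord_cols) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 1)
    if (length(bad) > 0) {
      stop("non-positive ", col, " in ", path, " row ", bad[1],
           " (protein ", df$protein_id[bad[1]], ")")
    }
  }
  if (all(c("start", "end") %in% names(df))) {
    bad <- which(!is.na(df$end) & df$end < df$start)
    if (length(bad) > 0) {
      stop("end < start in ", path, " row ", bad[1],
           " (protein ", df$protein_id[bad[1]], ")")
    }
  }
  if (!is.null(proteins)) {
    len <- setNames(nchar(proteins$sequence), proteins$id)
    unknown <- setdiff(unique(df$protein_id), names(len))
    if (length(unknown) > 0) {
      stop("table ", path, " references unknown protein id(s): ",
           paste(unknown, collapse = ", "))
    }
    hi <- if ("end" %in% names(df)) {
      ifelse(is.na(df$end), df$start, df$end)
    } else df$start
    bad <- which(hi > len[df$protein_id])
    if (length(bad) > 0) {
      stop("coordinate beyond protein length in ", path, " row ", bad[1],
           " (protein ", df$protein_id[bad[1]], ", position ", hi[bad[1]],
           " > length ", len[df$protein_id[bad[1]]], ")")
    }
  }
  invisible(df)
}

#' Write a pipeline table (TSV)
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param comment optional comment line (without the leading `#`) written
#'   above the header, used for provenance such as the run manifest hash.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Left-to-right leaf order of a newick tree
#'
#' Used only to order proteins in architecture plots the way the family's
#' phylogeny displays them.
#'
#' @param path path to a newick file.
#' @param ids optional character vector of family ids; when supplied, leaves
#'   absent from `ids` are dropped with a warning and the intersection is
#'   returned (in tree order).
#' @return Character vector of leaf labels in display order.
#' @export
read_tree_leaf_order <- function(path, ids = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("malformed newick file: ", path)
  tree <- ape::reorder.phylo(tree, "cladewise")
  tip_idx <- tree$edge[tree$edge[, 2] <= length(tree$tip.label), 2]
  leaves <- tree$tip.label[tip_idx]
  if (!is.null(ids) && !setequal(leaves, ids)) {
    warning("tree leaves and family ids differ; using their intersection (",
            length(intersect(leaves, ids)), " of ", length(ids), " ids)")
    leaves <- leaves[leaves %in% ids]
  }
  leaves
}

#' Convert a MEME plain-text report to motif occurrences
#'
#' Minimal adapter for the classic MEME text output: for each motif it reads
#' the "sites sorted by position p-value" block and emits rows in the
#' canonical `motifs` TSV schema. The TSV schema — not any particular MEME
#' version — is the pipeline's interface; use this only as a convenience.
#'
#' @param path path to a MEME plain-text report.
#' @return data.frame with columns `protein_id`, `motif_id`, `start`, `end`,
#'   `matched_seq`.
#' @export
read_meme_occurrences <- function(path) {
  lines <- readLines(path, warn = FALSE)
  head_re <- "^MOTIF\\s+(\\S+)(\\s+MEME-\\S+)?.*sites sorted by position p-value"
  alt_re  <- "^\\s*Motif\\s+(\\S+)\\s.*sites sorted by position p-value"
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    motif_id <- NA_character_
    if (grepl(head_re, lines[i])) {
      motif_id <- sub(head_re, "\\1", lines[i])
    } else if (grepl(alt_re, lines[i])) {
      motif_id <- sub(alt_re, "\\1", lines[i])
    }
    if (!is.na(motif_id)) {
      # skip the ruler/header lines up to the dashed separator, then read
      # rows until the next dashed separator
      j <- i + 1
      while (j <= length(lines) && !grepl("^-{5,}", lines[j])) j <- j + 1
      j <- j + 1
      while (j <= length(lines) && grepl("^Sequence name", lines[j])) j <- j + 1
      if (j <= length(lines) && grepl("^-{5,}", lines[j])) j <- j + 1
      while (j <= length(lines) && nzchar(trimws(lines[j])) &&
             !grepl("^-{5,}", lines[j])) {
        fields <- strsplit(trimws(lines[j]), "\\s+")[[1]]
        if (length(fields) >= 3 && grepl("^[0-9]+$", fields[2])) {
          start <- as.integer(fields[2])
          site <- fields[length(fields) - 1]
          if (!grepl("^[A-Za-z]+$", site)) site <- fields[length(fields)]
          out[[length(out) + 1]] <- data.frame(
            protein_id = fields[1], motif_id = motif_id,
            start = start, end = start + nchar(site) - 1L,
            matched_seq = toupper(site), stringsAsFactors = FALSE)
        }
        j <- j + 1
      }
      i <- j
    }
    i <- i + 1
  }
  if (length(out) == 0) {
    return(data.frame(protein_id = character(), motif_id = character(),
                      start = integer(), end = integer(),
                      matched_seq = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}
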
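# Swiss-Prot-style average amino-acid background frequencies.
AA_BACKGROUND <- c(
  A = 0.0825, C = 0.0137, D = 0.0545, E = 0.0675, F = 0.0386,
  G = 0.0707, H = 0.0227, I = 0.0596, K = 0.0584, L = 0.0966,
  M = 0.0242, N = 0.0406, P = 0.0473, Q = 0.0393, R = 0.0553,
  S = 0.0656, T = 0.0534, V = 0.0687, W = 0.0108, Y = 0.0292
)
AA_BACKGROUND <- AA_BACKGROUND / sum(AA_BACKGROUND)

# Synthetic HD + HALZ core consensus (103 residues). Positions 2, 3, 5,
# 47, 50, 51, 55 carry the family's key homeodomain residues
# (K, K, R, I, Q, N, R); the leucine-zipper part has a heptad Leu repeat.
CORE_CONSENSUS <- paste0(
  "RKKRRLSPEQ", "VESLEESFAT", "NPKPDSKTRA", "ELSKQLGLQP", "ERHQIAIWFQ",
  #           10           20           30           40           50
  "NRRARWKSKE", "RDY",                                   # HD: 63 aa
  "NLLKSEYDAL", "LSENDSLKAE", "NDKLSSELLL",              # HALZ: 40 aa
  "LSEKLSSKEK"
)

#' Default motif set of the synthetic family
#'
#' Each planted motif has a consensus string, the groups carrying it, the
#' region it lives in, a relative placement window within that region, a
#' per-member presence probability and a per-position consensus identity.
#' The defaults emulate a family whose distal CTR carries group-specific
#' Trp/Phe-rich acidic (AHA-like) motifs, whose proximal CTR carries a
#' Ser/acidic motif shared by several groups, and whose NTR carries a
#' basic motif restricted to one group; one group (VI) has no distinctive
#' CTR motif.
#'
#' @return A list of motif definitions.
#' @export
default_planted_motifs <- function() {
  aha <- function(id, groups, consensus) {
    list(id = id, consensus = consensus, groups = groups, region = "ctr",
         window = c(0.85, 1.0), presence = 0.9, identity = 0.95)
  }
  list(
    aha("aha_Ia", "Ia", "DELWDFLWE"),
    aha("aha_Ib", "Ib", "EDFWGDLWD"),
    aha("aha_Ic", "Ic", "DDWFPELWE"),
    aha("aha_II", "II", "EEWDGFDWD"),
    aha("aha_III", "III", "DFEWDPDWE"),
    aha("aha_IV", "IV", "EDWPDFEWD"),
    aha("aha_V", "V", "DEWFDGEWE"),
    aha("aha_Pp", "Pp", "EEFWDDPWE"),
    list(id = "prox_shared", consensus = "SDSEESSDS",
         groups = c("III", "IV", "V", "Pp"), region = "ctr",
         window = c(0.05, 0.45), presence = 0.85, identity = 0.95),
    list(id = "ntr_VI", consensus = "KRKRSPSSK", groups = "VI",
         region = "ntr", window = c(0.2, 0.8), presence = 0.9,
         identity = 0.95)
  )
}

#' Configuration of the synthetic protein family
#'
#' The defaults are the study conditions the analysis assumes: a
#' 178-member family split into six groups (I subdivided a/b/c) plus a
#' moss-like outgroup set and unassigned members; a highly conserved
#' 103-residue HD+HALZ core with per-column identity targets of 0.74,
#' 0.94, 0.93, 0.54 (with V as the alternative), 1.00, 0.99 and 1.00 at
#' homeodomain positions 2, 3, 5, 47, 50, 51 and 55; NTR lengths uniform
#' on \[19, 91\] and CTR lengths uniform on \[62, 127\]; group-specific
#' planted motifs ([default_planted_motifs()]); sumoylation-consensus
#' sites planted at 0.6 per CTR and 0.05 per NTR with hydrophobic-position
#' weights V/I/L/M/F = .62/.19/.11/.06/.02 and E:D = .84:.16; and a
#' 3-fold tryptophan enrichment in the terminal decile of the CTR.
#'
#' @param n_proteins family size.
#' @param group_proportions named numeric vector summing to 1.
#' @param core_consensus core consensus string.
#' @param column_identity named numeric vector, core position ->
#'   consensus-identity target; positions not listed use
#'   `default_identity`.
#' @param column_alternative named character vector, core position -> the
#'   single residue used for all non-consensus draws there (elsewhere
#'   non-consensus draws come from the background).
#' @param default_identity consensus identity of unlisted core columns.
#' @param ntr_length,ctr_length integer ranges `c(min, max)`.
#' @param motifs list of planted-motif definitions.
#' @param sumo_rate named vector: expected planted sites per NTR / CTR.
#' @param psi_weights,acidic_weights residue weights of the planted sites'
#'   hydrophobic first and acidic last positions.
#' @param trp_enrichment terminal-decile Trp enrichment factor (>= 1).
#' @param background background residue frequencies (sum to 1).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(
    n_proteins = 178L,
    group_proportions = c(Ia = 0.10, Ib = 0.08, Ic = 0.10, II = 0.12,
                          III = 0.10, IV = 0.10, V = 0.12, VI = 0.06,
                          Pp = 0.08, unassigned = 0.14),
    core_consensus = CORE_CONSENSUS,
    column_identity = c(`2` = 0.74, `3` = 0.94, `5` = 0.93, `47` = 0.54,
                        `50` = 1.00, `51` = 0.99, `55` = 1.00),
    column_alternative = c(`47` = "V"),
    default_identity = 0.85,
    ntr_length = c(19L, 91L),
    ctr_length = c(62L, 127L),
    motifs = default_planted_motifs(),
    sumo_rate = c(ntr = 0.05, ctr = 0.6),
    psi_weights = c(V = 0.62, I = 0.19, L = 0.11, M = 0.06, F = 0.02),
    acidic_weights = c(E = 0.84, D = 0.16),
    trp_enrichment = 3,
    background = AA_BACKGROUND) {
  stopifnot(
    n_proteins >= 1,
    abs(sum(group_proportions) - 1) < 1e-8,
    all(column_identity >= 0 & column_identity <= 1),
    default_identity >= 0, default_identity <= 1,
    ntr_length[1] >= 0, ntr_length[2] >= ntr_length[1],
    ctr_length[1] >= 0, ctr_length[2] >= ctr_length[1],
    trp_enrichment >= 1,
    abs(sum(background) - 1) < 1e-6,
    all(c("ntr", "ctr") %in% names(sumo_rate))
  )
  core_len <- nchar(core_consensus)
  if (any(as.integer(names(column_identity)) > core_len)) {
    stop("column_identity names a position beyond the core consensus")
  }
  for (m in motifs) {
    span <- (m$window[2] - m$window[1]) * ctr_length[1]
    if (m$region == "ctr" && span < nchar(m$consensus)) {
      stop("placement window of motif ", m$id,
           " is too small for the shortest CTR")
    }
    if (m$region == "ntr" &&
        (m$window[2] - m$window[1]) * ntr_length[1] < nchar(m$consensus)) {
      stop("placement window of motif ", m$id,
           " is too small for the shortest NTR")
    }
  }
  structure(list(
    n_proteins = as.integer(n_proteins),
    group_proportions = group_proportions,
    core_consensus = core_consensus,
    column_identity = column_identity,
    column_alternative = column_alternative,
    default_identity = default_identity,
    ntr_length = as.integer(ntr_length), ctr_length = as.integer(ctr_length),
    motifs = motifs, sumo_rate = sumo_rate,
    psi_weights = psi_weights / sum(psi_weights),
    acidic_weights = acidic_weights / sum(acidic_weights),
    trp_enrichment = trp_enrichment,
    background = background / sum(background)
  ), class = "simulation_config")
}

draw_background <- function(n, freqs) {
  if (n == 0) return(character(0))
  sample(names(freqs), n, replace = TRUE, prob = freqs)
}

# Background frequencies of the terminal CTR decile: W boosted by the
# enrichment factor, other residues scaled down proportionally.
terminal_freqs <- function(background, factor) {
  w <- min(background[["W"]] * factor, 0.9)
  out <- background * (1 - w) / (1 - background[["W"]])
  out[["W"]] <- w
  out
}

#' Simulate a protein family with planted ground truth
#'
#' Builds each protein as NTR + core + CTR: flank residues drawn from the
#' background (with the terminal-decile Trp boost in the CTR), core
#' residues drawn per column at the configured consensus identity, then
#' group-assigned motifs and sumoylation-consensus sites planted by
#' overwriting flank positions (sites never overlap planted motifs or each
#' other; rejection sampling). Deterministic given `(config, seed)`.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed; recorded in the result.
#' @return An object of class `simulated_family`: list with `proteins`
#'   (id, sequence, group), `domains` (HD and HALZ hit rows), `groups`,
#'   `truth_motifs`, `truth_sites` (whole-protein coordinates, `motifs`
#'   schema with a `kind` column), and `seed`.
#' @export
simulate_family <- function(config = simulation_config(), seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(as.integer(seed), simulate_family_impl(config, seed))
}

simulate_family_impl <- function(config, seed) {
  n <- config$n_proteins
  core_len <- nchar(config$core_consensus)
  consensus <- strsplit(config$core_consensus, "")[[1]]
  identity <- rep(config$default_identity, core_len)
  identity[as.integer(names(config$column_identity))] <- config$column_identity
  groups <- sample(names(config$group_proportions), n, replace = TRUE,
                   prob = config$group_proportions)
  ids <- sprintf("SYN%03d", seq_len(n))
  proteins <- vector("list", n)
  domains <- vector("list", n)
  truth_motifs <- list()
  truth_sites <- list()
  for (i in seq_len(n)) {
    ntr_len <- sample(config$ntr_length[1]:config$ntr_length[2], 1)
    ctr_len <- sample(config$ctr_length[1]:config$ctr_length[2], 1)
    ntr <- draw_background(ntr_len, config$background)
    # CTR background with terminal-decile Trp enrichment
    dec_start <- ctr_len - ceiling(ctr_len / 10) + 1
    ctr <- character(ctr_len)
    if (dec_start > 1) {
      ctr[1:(dec_start - 1)] <- draw_background(dec_start - 1,
                                                config$background)
    }
    tf <- terminal_freqs(config$background, config$trp_enrichment)
    ctr[dec_start:ctr_len] <- draw_background(ctr_len - dec_start + 1, tf)
    # core columns at configured identity
    # identity[j] is exactly the probability of the consensus residue:
    # non-consensus draws exclude it (renormalized background)
    core <- vapply(seq_len(core_len), function(j) {
      if (runif(1) <= identity[j]) return(consensus[j])
      alt <- config$column_alternative[as.character(j)]
      if (!is.na(alt)) return(unname(alt))
      bg <- config$background[setdiff(names(config$background), consensus[j])]
      draw_background(1, bg / sum(bg))
    }, character(1))
    occupied <- list(ntr = integer(0), ctr = integer(0))
    # plant group-assigned motifs
    for (m in config$motifs) {
      if (!groups[i] %in% m$groups) next
      if (runif(1) > m$presence) next
      reg_len <- if (m$region == "ntr") ntr_len else ctr_len
      mlen <- nchar(m$consensus)
      lo <- max(1L, ceiling(m$window[1] * reg_len))
      hi <- min(reg_len, floor(m$window[2] * reg_len)) - mlen + 1L
      if (hi < lo) next
      start <- if (hi == lo) lo else sample(lo:hi, 1)
      mres <- strsplit(m$consensus, "")[[1]]
      planted <- vapply(seq_len(mlen), function(j) {
        if (runif(1) <= m$identity) mres[j] else
          draw_background(1, config$background)
      }, character(1))
      pos <- start:(start + mlen - 1L)
      if (m$region == "ntr") ntr[pos] <- planted else ctr[pos] <- planted
      occupied[[m$region]] <- c(occupied[[m$region]], pos)
      offset <- if (m$region == "ntr") 0L else ntr_len + core_len
      truth_motifs[[length(truth_motifs) + 1]] <- data.frame(
        protein_id = ids[i], motif_id = m$id,
        start = as.integer(offset + start),
        end = as.integer(offset + start + mlen - 1L),
        matched_seq = paste(planted, collapse = ""),
        region = toupper(sub("ntr", "NTR", sub("ctr", "CTR", m$region))),
        stringsAsFactors = FALSE)
    }
    # plant sumoylation-consensus sites (Psi-K-x-E/D), avoiding motifs
    for (region in c("ntr", "ctr")) {
      reg_len <- if (region == "ntr") ntr_len else ctr_len
      if (reg_len < 4) next
      n_sites <- rpois(1, config$sumo_rate[[region]])
      for (s in seq_len(n_sites)) {
        placed <- FALSE
        for (try in 1:50) {
          start <- sample(seq_len(reg_len - 3L), 1)
          pos <- start:(start + 3L)
          if (any(pos %in% occupied[[region]])) next
          site <- c(
            sample(names(config$psi_weights), 1, prob = config$psi_weights),
            "K",
            draw_background(1, config$background),
            sample(names(config$acidic_weights), 1,
                   prob = config$acidic_weights))
          if (region == "ntr") ntr[pos] <- site else ctr[pos] <- site
          occupied[[region]] <- c(occupied[[region]], pos)
          offset <- if (region == "ntr") 0L else ntr_len + core_len
          truth_sites[[length(truth_sites) + 1]] <- data.frame(
            protein_id = ids[i], motif_id = "sumo_site",
            start = as.integer(offset + start),
            end = as.integer(offset + start + 3L),
            matched_seq = paste(site, collapse = ""),
            region = toupper(region), stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed) {
          warning("could not place a site in ", ids[i], " ", region,
                  " after 50 tries")
        }
      }
    }
    proteins[[i]] <- data.frame(
      id = ids[i],
      sequence = paste(c(ntr, core, ctr), collapse = ""),
      group = groups[i], stringsAsFactors = FALSE)
    hd_end <- ntr_len + 63L
    domains[[i]] <- data.frame(
      protein_id = rep(ids[i], 2), domain = c("HD", "HALZ"),
      start = c(ntr_len + 1L, ntr_len + 58L),
      end = c(hd_end, ntr_len + core_len),
      score = c(NA_real_, NA_real_), stringsAsFactors = FALSE)
  }
  empty_truth <- data.frame(protein_id = character(), motif_id = character(),
                            start = integer(), end = integer(),
                            matched_seq = character(), region = character(),
                            stringsAsFactors = FALSE)
  proteins <- do.call(rbind, proteins)
  structure(list(
    proteins = proteins,
    domains = do.call(rbind, domains),
    groups = data.frame(protein_id = proteins$id, group = proteins$group,
                        stringsAsFactors = FALSE),
    truth_motifs = if (length(truth_motifs)) do.call(rbind, truth_motifs)
                   else empty_truth,
    truth_sites = if (length(truth_sites)) do.call(rbind, truth_sites)
                  else empty_truth,
    config = config, seed = as.integer(seed)
  ), class = "simulated_family")
}

#' @export
print.simulated_family <- function(x, ...) {
  cat("<simulated_family> ", nrow(x$proteins), " proteins (seed ", x$seed,
      "); ", nrow(x$truth_motifs), " planted motif occurrence(s), ",
      nrow(x$truth_sites), " planted site(s)\n", sep = "")
  invisible(x)
}

#' Write a simulated family to disk
#'
#' Writes `family.fasta`, `domains.tsv`, `groups.tsv`, `truth_motifs.tsv`
#' and `truth_sites.tsv`; every table carries the seed in a header comment.
#'
#' @param sim a `simulated_family`.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$proteins, file.path(out_dir, "family.fasta"))
  comment <- paste0("flankscan simulate seed=", sim$seed)
  write_table(sim$domains, file.path(out_dir, "domains.tsv"), comment)
  write_table(sim$groups, file.path(out_dir, "groups.tsv"), comment)
  write_table(sim$truth_motifs, file.path(out_dir, "truth_motifs.tsv"), comment)
  write_table(sim$truth_sites, file.path(out_dir, "truth_sites.tsv"), comment)
  invisible(out_dir)
}

#' Expected per-window match rate of a pattern under background frequencies
#'
#' The closed-form probability that one window matches: the product over
#' pattern positions of the summed frequencies of that position's allowed
#' residues.
#'
#' @param pattern a `consensus_pattern` or source string.
#' @param background named frequency vector over the 20 standard residues
#'   (defaults to the simulator's background).
#' @return Probability per window.
#' @export
analytic_background_rate <- function(pattern, background = AA_BACKGROUND) {
  pattern <- as_pattern(pattern)
  background <- background / sum(background)
  prod(vapply(pattern$positions, function(p) {
    sum(background[p])
  }, numeric(1)))
}
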
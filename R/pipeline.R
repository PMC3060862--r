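#' Default pipeline parameters
#'
#' The analysis-wide defaults: the sumoylation canonical and control
#' consensus patterns, tryptophan as the focal composition residue with 10
#' bins, score cutoffs 0.9 (phosphorylation) and 0.6 (NLS), the
#' proximal/distal boundary fraction 0.5, and the all-sequences
#' conservation denominator.
#'
#' @return Named list of parameters.
#' @export
default_parameters <- function() {
  list(
    pattern = "[FVIML]-K-x-[ED]",
    control = "[FVIML]-K-x-{ED}",
    residue = "W",
    bins = 10L,
    boundary = 0.5,
    cutoffs = c(phospho = 0.9, nls = 0.6),
    denominator = "all",
    require_halz = TRUE
  )
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a YAML file path or a list")
  params <- utils::modifyList(default_parameters(), config$parameters %||% list())
  if (!is.null(params$cutoffs)) params$cutoffs <- unlist(params$cutoffs)
  config$parameters <- params
  if (is.null(config$inputs) && is.null(config$simulate)) {
    stop("config must declare either 'inputs' (fasta + domains) or 'simulate'")
  }
  if (!is.null(config$inputs)) {
    for (field in c("fasta", "domains")) {
      if (is.null(config$inputs[[field]])) {
        stop("stage partition: config inputs lack required field '", field, "'")
      }
    }
  }
  config
}

#' Run the whole flanking-region analysis pipeline
#'
#' Stages, in dependency order: (optional) family simulation; region
#' partitioning; canonical/control consensus scans of the NTRs and CTRs;
#' the focal-residue composition profile of the CTRs; conservation of the
#' core-domain columns (or of a supplied alignment); and — when motif
#' occurrence tables, group labels or site predictions are supplied —
#' architecture localization, group specificity, AHA features and site
#' overlays. All artifacts and a reproducibility manifest are written to
#' `out_dir`.
#'
#' @param config YAML file path or list. Fields: `seed` (integer);
#'   either `simulate: yes` (optionally with simulator overrides
#'   `n_proteins`, `trp_enrichment`, ...) or `inputs:` with `fasta`,
#'   `domains` and optional `groups`, `motifs`, `sites`, `alignment`,
#'   `tree`; and optional `parameters:` overriding [default_parameters()].
#' @param out_dir output directory.
#' @return Invisibly, a list with all stage results plus the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- read_pipeline_config(config)
  params <- config$parameters
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    tool = "flankscan", version = as.character(packageVersion("flankscan")),
    seed = seed, parameters = params[c("pattern", "control", "residue",
                                       "bins", "boundary", "denominator")],
    cutoffs = as.list(params$cutoffs), inputs = list()
  )

  groups <- motifs <- sites <- alignment <- leaf_order <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (isTRUE(sim_args) || identical(sim_args, "yes")) sim_args <- list()
    cfg <- do.call(simulation_config, sim_args)
    sim <- simulate_family(cfg, seed)
    sim_dir <- file.path(out_dir, "simulated")
    write_simulation(sim, sim_dir)
    proteins <- sim$proteins
    domains <- sim$domains
    groups <- sim$groups
    manifest$inputs$simulated <- sim_dir
  } else {
    inp <- config$inputs
    proteins <- read_fasta(inp$fasta)
    domains <- read_table(inp$domains, "domains", proteins)
    if (!is.null(inp$groups)) groups <- read_table(inp$groups, "groups")
    if (!is.null(inp$motifs)) motifs <- read_table(inp$motifs, "motifs", proteins)
    if (!is.null(inp$sites)) sites <- read_table(inp$sites, "sites", proteins)
    if (!is.null(inp$alignment)) alignment <- read_alignment(inp$alignment)
    if (!is.null(inp$tree)) {
      leaf_order <- read_tree_leaf_order(inp$tree, ids = proteins$id)
    }
    present <- !vapply(inp, is.null, logical(1))
    manifest$inputs <- lapply(inp[present], function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    })
  }

  cfg_file <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config[setdiff(names(config), "parameters")], cfg_file)
  manifest$config_md5 <- unname(tools::md5sum(cfg_file))
  stamp <- paste0("flankscan v", manifest$version, " seed=", seed,
                  " config_md5=", manifest$config_md5)

  # --- partition ---------------------------------------------------------
  partitions <- partition_family(proteins, domains,
                                 require_halz = params$require_halz)
  write_region_fasta(proteins, partitions, out_dir, comment = stamp)

  # --- consensus scans ---------------------------------------------------
  scans <- list()
  for (region in c("ntr", "ctr")) {
    seqs <- region_sequences(proteins, partitions, region)
    if (length(seqs) == 0) next
    enr <- enrichment_summary(seqs, params$pattern, params$control)
    scans[[region]] <- enr
    write_table(enr$occurrences,
                file.path(out_dir, paste0("occurrences_", region, ".tsv")),
                comment = stamp)
  }
  jsonlite::write_json(
    lapply(scans, function(e) {
      list(pattern = e$pattern, control = e$control_pattern,
           n_sequences = e$n_sequences, n_occurrences = e$n_occurrences,
           n_proteins_with_hit = e$n_proteins_with_hit,
           n_control_occurrences = e$n_control_occurrences,
           n_control_proteins = e$n_control_proteins,
           ratio = round(e$ratio, 2),
           position_percent = lapply(e$position_percent, as.list))
    }),
    file.path(out_dir, "enrichment.json"), auto_unbox = TRUE, pretty = TRUE)

  # --- composition -------------------------------------------------------
  ctr_seqs <- region_sequences(proteins, partitions, "ctr")
  profile <- decile_histogram(ctr_seqs, params$residue, k = params$bins)
  write_table(as.data.frame(profile), file.path(out_dir, "histogram.tsv"),
              comment = stamp)

  # --- conservation ------------------------------------------------------
  cons_aln <- alignment %||% region_sequences(proteins, partitions, "core")
  cons <- logo <- NULL
  if (length(unique(nchar(cons_aln))) == 1) {
    cons <- column_profile(cons_aln)
    logo <- region_logo(cons_aln)
    write_table(
      data.frame(column = seq_len(cons$width),
                 gap_fraction = cons$gap_fraction, ic = logo$ic),
      file.path(out_dir, "conservation.tsv"), comment = stamp)
    write_table(cbind(residue = rownames(logo$pfm),
                      as.data.frame(round(logo$pfm, 6))),
                file.path(out_dir, "pfm.tsv"), comment = stamp)
  } else {
    warning("core sequences have unequal lengths and no alignment was ",
            "supplied; conservation stage skipped")
  }

  # --- architecture ------------------------------------------------------
  architecture <- specificity <- overlaps <- NULL
  if (!is.null(config$simulate)) motifs <- sim$truth_motifs
  if (!is.null(motifs) && nrow(motifs) > 0) {
    architecture <- localize_occurrences(
      motifs[, intersect(c("protein_id", "motif_id", "start", "end",
                           "matched_seq"), names(motifs))],
      partitions, boundary = params$boundary)
    write_table(architecture, file.path(out_dir, "architecture.tsv"),
                comment = stamp)
    if (!is.null(groups)) {
      specificity <- group_specificity(architecture, groups)
      spec_df <- as.data.frame.table(
        as.table(specificity$member_fraction),
        responseName = "member_fraction")
      names(spec_df)[1:2] <- c("motif_id", "group")
      spec_df$occurrence_fraction <- as.data.frame.table(
        as.table(specificity$occurrence_fraction))$Freq
      write_table(spec_df, file.path(out_dir, "specificity.tsv"),
                  comment = stamp)
    }
    distal <- architecture[!is.na(architecture$ctr_zone) &
                             architecture$ctr_zone == "distal", , drop = FALSE]
    if (nrow(distal) > 0) {
      aha_by_motif <- lapply(split(distal$matched_seq, distal$motif_id),
                             aha_features)
      jsonlite::write_json(
        lapply(aha_by_motif, function(a) {
          list(n = a$n_sequences, acidic_fraction = a$acidic_fraction,
               mean_terminal_trp = a$mean_terminal_trp,
               flags = as.list(a$flags))
        }),
        file.path(out_dir, "aha.json"), auto_unbox = TRUE, pretty = TRUE)
    }
  }
  if (!is.null(sites)) {
    overlaps <- overlay_sites(partitions, sites, annotations = architecture,
                              cutoffs = params$cutoffs)
    ov <- as.data.frame(overlaps$by_region)
    names(ov) <- c("kind", "region", "n_sites")
    write_table(ov, file.path(out_dir, "overlaps.tsv"), comment = stamp)
  }

  manifest$stages <- c("partition", "scan", "composition", "conserve",
                       if (!is.null(architecture)) "architecture")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(
    proteins = proteins, partitions = partitions, scans = scans,
    profile = profile, conservation = cons, logo = logo,
    architecture = architecture, specificity = specificity,
    overlaps = overlaps, leaf_order = leaf_order, manifest = manifest
  ))
}
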
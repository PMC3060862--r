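small_config <- function(...) {
  simulation_config(n_proteins = 30L, ...)
}

test_that("simulation is deterministic given config and seed", {
  sim1 <- simulate_family(small_config(), seed = 42)
  sim2 <- simulate_family(small_config(), seed = 42)
  expect_identical(sim1$proteins, sim2$proteins)
  expect_identical(sim1$truth_sites, sim2$truth_sites)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(sim1, d1)
  write_simulation(sim2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  sim3 <- simulate_family(small_config(), seed = 43)
  expect_false(identical(sim1$proteins, sim3$proteins))
})

test_that("truth tables satisfy the I/O schemas and coordinate contracts", {
  sim <- simulate_family(small_config(), seed = 5)
  expect_equal(anyDuplicated(sim$proteins$id), 0)
  for (truth in list(sim$domains, sim$truth_motifs, sim$truth_sites)) {
    expect_silent(flankscan:::validate_coordinates(truth, "motifs",
                                                   sim$proteins))
  }
  # planted sites match the canonical consensus exactly, and the recorded
  # matched_seq equals the protein subsequence
  expect_true(all(grepl("^[FVIML]K[A-Z][ED]$", sim$truth_sites$matched_seq)))
  seqs <- setNames(sim$proteins$sequence, sim$proteins$id)
  expect_equal(
    substr(seqs[sim$truth_sites$protein_id],
           sim$truth_sites$start, sim$truth_sites$end),
    sim$truth_sites$matched_seq, ignore_attr = TRUE)
  expect_equal(
    substr(seqs[sim$truth_motifs$protein_id],
           sim$truth_motifs$start, sim$truth_motifs$end),
    sim$truth_motifs$matched_seq, ignore_attr = TRUE)
})

test_that("a fully conserved column reports 100% and partitions recover the core", {
  cfg <- small_config(column_identity = c(`50` = 1.0))
  sim <- simulate_family(cfg, seed = 6)
  parts <- partition_family(sim$proteins, sim$domains)
  expect_equal(parts$ntr_length + parts$core_length + parts$ctr_length,
               parts$length)
  expect_equal(unique(parts$core_length), nchar(cfg$core_consensus))
  core <- region_sequences(sim$proteins, parts, "core")
  rep <- key_residue_report(core, c(Q50 = 50), c(Q50 = "Q"))
  expect_equal(rep$percent, 100)
})

test_that("analytic background rates follow the closed form", {
  uniform <- setNames(rep(1 / 20, 20), AA20)
  expect_equal(analytic_background_rate("[FVIML]-K-x-[ED]", uniform),
               (5 / 20) * (1 / 20) * 1 * (2 / 20))
  expect_equal(analytic_background_rate("x", uniform), 1)
  expect_equal(analytic_background_rate("[FVIML]-K-x-{ED}", uniform),
               (5 / 20) * (1 / 20) * 1 * (18 / 20))
  # with the simulator's default background the two rates still partition
  # the relaxed pattern's rate
  expect_equal(analytic_background_rate("[FVIML]-K-x-[ED]") +
                 analytic_background_rate("[FVIML]-K-x-{ED}"),
               analytic_background_rate("[FVIML]-K-x-x"))
})

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(group_proportions = c(a = 0.5, b = 0.4)))
  expect_error(simulation_config(trp_enrichment = 0.5))
  expect_error(
    simulation_config(motifs = list(list(
      id = "too_big", consensus = strrep("W", 30), groups = "II",
      region = "ctr", window = c(0.9, 1.0), presence = 1, identity = 1))),
    "too small")
  expect_error(
    simulation_config(column_identity = c(`200` = 0.9)),
    "beyond the core consensus")
})

test_that("terminal-decile Trp planting shows up as last-bin enrichment", {
  cfg <- simulation_config(n_proteins = 150L, trp_enrichment = 4,
                           motifs = list(), sumo_rate = c(ntr = 0, ctr = 0))
  sim <- simulate_family(cfg, seed = 7)
  parts <- partition_family(sim$proteins, sim$domains)
  h <- decile_histogram(region_sequences(sim$proteins, parts, "ctr"), "W")
  expect_equal(unname(which.max(h$frequency)), 10L)
  w_bg <- cfg$background[["W"]]
  expect_equal(unname(h$frequency[10]) / w_bg, 4, tolerance = 0.35)
  expect_lt(max(h$frequency[1:9]), h$frequency[10] / 2)
})
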
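make_partition <- function() {
  # NTR [1,19], core [20,80], CTR [81,100]
  fam <- toy_family()
  partition_family(fam$proteins, fam$domains)[1, ]
}

test_that("occurrences are localized by midpoint with proximal/distal zoning", {
  parts <- make_partition()
  occ <- data.frame(protein_id = "P1", motif_id = c("m1", "m2", "m3"),
                    start = c(85L, 95L, 30L), end = c(95L, 100L, 40L),
                    stringsAsFactors = FALSE)
  ann <- localize_occurrences(occ, parts)
  # midpoint 90 of [85,95] -> relative (90 - 81 + 0.5)/20 = 0.475 -> proximal
  expect_equal(ann$region[1], "CTR")
  expect_equal(ann$relative_position[1], 0.475)
  expect_equal(ann$ctr_zone[1], "proximal")
  # occurrence ending at the protein's last residue -> distal
  expect_equal(ann$ctr_zone[2], "distal")
  # occurrence inside the core: region = core, no CTR zone
  expect_equal(ann$region[3], "core")
  expect_true(is.na(ann$ctr_zone[3]))
  expect_equal(ann$region_start[3], 11L)
})

test_that("boundary-spanning occurrences are flagged, and each occurrence gets exactly one region", {
  parts <- make_partition()
  occ <- data.frame(protein_id = "P1", motif_id = "m",
                    start = 78L, end = 84L, stringsAsFactors = FALSE)
  expect_warning(ann <- localize_occurrences(occ, parts), "span")
  expect_true(ann$spans_boundary)
  expect_equal(ann$region, "CTR")  # midpoint 81 lies in the CTR
  withr::local_seed(21)
  many <- data.frame(protein_id = "P1", motif_id = "r",
                     start = s <- sample(1:95, 40, replace = TRUE),
                     end = pmin(s + 5L, 100L), stringsAsFactors = FALSE)
  ann2 <- suppressWarnings(localize_occurrences(many, parts))
  expect_equal(nrow(ann2), 40)
  expect_true(all(ann2$region %in% c("NTR", "core", "CTR")))
  expect_true(all(ann2$relative_position >= 0 & ann2$relative_position <= 1))
})

test_that("group specificity flags single-group motifs and not shared ones", {
  groups <- data.frame(
    protein_id = sprintf("P%02d", 1:40),
    group = rep(c("II", "III", "IV", "V"), each = 10))
  # motif A in 9/10 group II members; motif B in most of III, IV and V
  occ <- rbind(
    data.frame(protein_id = sprintf("P%02d", 1:9), motif_id = "A"),
    data.frame(protein_id = sprintf("P%02d", 11:38), motif_id = "B"))
  spec <- group_specificity(occ, groups)
  expect_equal(unname(spec$characteristic["A"]), "II")
  expect_true(is.na(spec$characteristic["B"]))
  expect_equal(unname(spec$member_fraction["A", "II"]), 0.9)
  expect_equal(unname(spec$occurrence_fraction["A", "II"]), 1)
  expect_equal(unname(rowSums(spec$occurrence_fraction)), c(1, 1))
  # unlabeled proteins fall into "unassigned"; empty groups warn
  occ2 <- rbind(occ, data.frame(protein_id = "P99", motif_id = "A"))
  spec2 <- group_specificity(occ2, groups)
  expect_true("unassigned" %in% colnames(spec2$member_fraction))
  groups3 <- rbind(groups, data.frame(protein_id = "P41", group = "VI"))
  expect_silent(spec3 <- group_specificity(occ, groups3))
  expect_equal(unname(spec3$member_fraction["A", "VI"]), 0)
})

test_that("AHA features count aromatics, acidic context and terminal Trp", {
  a <- aha_features("DDWFDE")
  expect_equal(a$aromatic_freq, c(0, 0, 1, 1, 0, 0))
  expect_equal(a$acidic_fraction, 4 / 6)
  expect_true(a$flags[["aromatic_core"]])
  expect_true(a$flags[["acidic_context"]])
  # poly-A: nothing fires
  b <- aha_features("AAAAAA")
  expect_equal(b$acidic_fraction, 0)
  expect_false(any(b$flags))
  # synthetic HAHB4-like terminus: two terminal Trp next to a basic residue
  h <- aha_features("DEDEDSSEDWKW")
  expect_equal(h$terminal_trp_counts, 2L, ignore_attr = TRUE)
  expect_true(h$flags[["basic_adjacent"]])
  expect_error(aha_features(character(0)), "at least one")
})

test_that("site overlays honor cutoffs and locate sites in motifs and regions", {
  parts <- make_partition()
  ann <- localize_occurrences(
    data.frame(protein_id = "P1", motif_id = "m1", start = 85L, end = 95L),
    parts)
  sites <- data.frame(
    protein_id = "P1", kind = c("phospho", "phospho", "phospho", "nls"),
    start = c(90L, 5L, 50L, 10L), end = c(NA, NA, NA, 18L),
    residue = c("S", "S", "T", NA), score = c(0.95, 0.89, 0.92, 0.7))
  ov <- overlay_sites(parts, sites, annotations = ann)
  # score 0.89 filtered at the 0.9 phospho cutoff
  expect_equal(nrow(ov$retained_sites), 3)
  expect_equal(unname(ov$by_motif["m1"]), 1L)
  expect_equal(as.vector(ov$by_region["phospho", c("NTR", "core", "CTR")]),
               c(0, 1, 1))
  expect_equal(ov$nls_regions$region, "NTR")
  # empty prediction table -> all-zero overlap counts
  ov0 <- overlay_sites(parts, sites[0, ], annotations = ann)
  expect_equal(sum(ov0$by_region), 0)
  expect_equal(unname(ov0$by_motif["m1"]), 0L)
  # counts are monotone non-increasing in the cutoff
  counts <- vapply(c(0.5, 0.9, 0.95, 0.99), function(cut) {
    nrow(overlay_sites(parts, sites,
                       cutoffs = c(phospho = cut, nls = 0.6))$retained_sites)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(overlay_sites(parts, transform(sites, kind = "glyco")),
               "no cutoff")
})

test_that("architecture and profile plots build without evaluation errors", {
  fam <- toy_family()
  parts <- partition_family(fam$proteins, fam$domains)
  ann <- localize_occurrences(
    data.frame(protein_id = c("P1", "P3"), motif_id = "m1",
               start = c(85L, 72L), end = c(95L, 78L)), parts)
  g <- plot_architecture(ann, parts, leaf_order = c("P3", "P1", "P2"))
  expect_s3_class(g, "ggplot")
  expect_silent(ggplot2::ggplot_build(g))
  h <- decile_histogram(c("AWAAAAAWWA", "AAAAWAAAAW"), "W")
  expect_s3_class(plot_decile_profile(h), "ggplot")
})
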
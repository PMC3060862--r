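test_that("PROSITE-style pattern compilation materializes position sets", {
  p <- compile_pattern("[FVIML]-K-x-[ED]")
  expect_equal(p$length, 4)
  expect_setequal(p$positions[[1]], c("F", "V", "I", "M", "L"))
  expect_equal(p$positions[[2]], "K")
  expect_equal(sort(p$positions[[3]]), sort(AA20))
  expect_setequal(p$positions[[4]], c("E", "D"))
  expect_equal(render_pattern(p), "[FVIML]-K-x-[ED]")

  px <- compile_pattern("x")
  expect_equal(px$length, 1)
  expect_equal(nrow(scan_sequence("QWERTY", px)), 6)

  ctl <- compile_pattern("[FVIML]-K-x-{ED}")
  expect_equal(length(ctl$positions[[4]]), 18)
  expect_false(any(c("E", "D") %in% ctl$positions[[4]]))
})

test_that("malformed patterns fail with positioned parse errors", {
  expect_error(compile_pattern("[FVIML]-K-[]-E"), "element 3")
  expect_error(compile_pattern("A--K"), "stray")
  expect_error(compile_pattern("A-kq-E"), "element 2")
  expect_error(compile_pattern("{ACDEFGHIKLMNPQRSTVWY}"), "excludes every")
})

test_that("scanning reports all overlapping matches in ascending order", {
  hits <- scan_sequence("MVKAEIKLDW", "[FVIML]-K-x-[ED]")
  expect_equal(hits$start, c(2L, 6L))
  expect_equal(hits$matched_seq, c("VKAE", "IKLD"))
  expect_equal(nrow(scan_sequence("MVKAEIKLDW", "[FVIML]-K-x-{ED}")), 0)
  expect_equal(scan_sequence("VKIE", "[FVIML]-K-x-[ED]")$start, 1L)
  expect_equal(nrow(scan_sequence("VK", "[FVIML]-K-x-[ED]")), 0)
  # overlapping self-matches are all counted
  expect_equal(scan_sequence("KAKAK", "K-x-K")$start, c(1L, 3L))
})

test_that("the scanner agrees with the brute-force window oracle", {
  withr::local_seed(101)
  patterns <- list(
    canonical = list(src = "[FVIML]-K-x-[ED]", sets = SUMO_SETS_CANONICAL),
    control = list(src = "[FVIML]-K-x-{ED}", sets = SUMO_SETS_CONTROL),
    mixed = list(src = "S-x-{P}-[DE]-x",
                 sets = list("S", structure(AA20, any = TRUE),
                             setdiff(AA20, "P"), c("D", "E"),
                             structure(AA20, any = TRUE)))
  )
  for (rep in 1:300) {
    s <- random_aa_seq(sample(1:200, 1), x_rate = 0.02)
    for (p in patterns) {
      expect_identical(scan_sequence(s, p$src)$start, brute_scan(s, p$sets),
                       label = paste("pattern", p$src, "on", s))
    }
  }
})

test_that("canonical and control matches partition the relaxed pattern's", {
  withr::local_seed(202)
  for (rep in 1:100) {
    s <- random_aa_seq(sample(4:150, 1))
    can <- scan_sequence(s, "[FVIML]-K-x-[ED]")$start
    ctl <- scan_sequence(s, "[FVIML]-K-x-{ED}")$start
    all4 <- scan_sequence(s, "[FVIML]-K-x-x")$start
    expect_length(intersect(can, ctl), 0)
    expect_identical(sort(union(can, ctl)), all4)
  }
})

test_that("enrichment summaries tally occurrences, proteins and positions", {
  seqs <- c(P1 = "MVKAEIKLDW",   # VKAE + IKLD
            P2 = "AAVKIEAA",     # VKIE
            P3 = "AAAKQAA",      # nothing (no hydrophobic before K)
            P4 = "FKYKLKTE")     # FKYK (control), LKTE (canonical)
  e <- enrichment_summary(seqs, "[FVIML]-K-x-[ED]", "[FVIML]-K-x-{ED}")
  expect_equal(e$n_occurrences, 4)
  expect_equal(e$n_proteins_with_hit, 3)
  expect_equal(e$n_control_occurrences, 1)
  expect_equal(e$n_control_proteins, 1)
  expect_equal(e$ratio, 4)
  # per-position identity distributions sum to the occurrence count
  for (tab in e$position_counts) expect_equal(sum(tab), e$n_occurrences)
  expect_equal(as.vector(e$position_counts[[1]][c("V", "I", "L", "F")]),
               c(2L, 1L, 1L, 0L))
  expect_equal(unname(e$position_percent[[4]][["E"]]), 75)  # 3 of 4
})

test_that("degenerate enrichment inputs stay defined", {
  expect_warning(e <- enrichment_summary(c(A = "AAAAAA", B = "CCCCCC"),
                                         "[FVIML]-K-x-[ED]",
                                         "[FVIML]-K-x-{ED}"),
                 "ratio undefined")
  expect_equal(e$n_occurrences, 0)
  expect_true(is.na(e$ratio))
  expect_error(enrichment_summary(character(0), "K", "R"), "at least one")
})
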
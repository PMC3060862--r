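# Shared fixtures and the independent brute-force scan oracle.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Window-by-window set-membership oracle, independent of the package's
# regex-based scanner. `sets` is a list of allowed-residue vectors; an
# element with attr(x, "any") accepts every character.
brute_scan <- function(sequence, sets) {
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  k <- length(sets)
  if (L < k) return(integer(0))
  starts <- integer(0)
  for (s in seq_len(L - k + 1)) {
    ok <- TRUE
    for (j in seq_len(k)) {
      set <- sets[[j]]
      if (isTRUE(attr(set, "any"))) next
      if (!(chars[s + j - 1] %in% set)) {
        ok <- FALSE
        break
      }
    }
    if (ok) starts <- c(starts, s)
  }
  starts
}

# Hand-built position sets of the sumoylation canonical / control patterns
# (independent of compile_pattern()).
SUMO_SETS_CANONICAL <- list(
  c("F", "V", "I", "M", "L"), "K",
  structure(AA20, any = TRUE), c("E", "D"))
SUMO_SETS_CONTROL <- list(
  c("F", "V", "I", "M", "L"), "K",
  structure(AA20, any = TRUE), setdiff(AA20, c("E", "D")))

random_aa_seq <- function(len, x_rate = 0) {
  letters_pool <- AA20
  s <- sample(letters_pool, len, replace = TRUE)
  if (x_rate > 0) {
    flip <- runif(len) < x_rate
    s[flip] <- "X"
  }
  paste(s, collapse = "")
}

# A small hand-checkable family: 3 proteins with HD/HALZ hits.
toy_family <- function() {
  proteins <- data.frame(
    id = c("P1", "P2", "P3"),
    sequence = c(
      paste0(strrep("A", 19), strrep("Q", 61), "VKIEW",
             strrep("S", 15)),                       # L = 100, CTR = [81,100]
      paste0(strrep("G", 10), strrep("Q", 50), strrep("T", 20)),  # L = 80
      paste0(strrep("N", 30), strrep("Q", 40), strrep("W", 10))   # L = 80
    ),
    stringsAsFactors = FALSE)
  domains <- data.frame(
    protein_id = rep(c("P1", "P2", "P3"), each = 2),
    domain = rep(c("HD", "HALZ"), 3),
    start = c(20L, 70L, 11L, 45L, 31L, 55L),
    end = c(76L, 80L, 50L, 60L, 56L, 70L),
    score = NA_real_, stringsAsFactors = FALSE)
  list(proteins = proteins, domains = domains)
}

supplementary_file <- function(...) {
  system.file("extdata", "supplementary", ..., package = "flankscan")
}

missing_supplementary <- function(what) {
  paste0(what, " is third-party supplementary data not bundled with the ",
         "package; place the file(s) under inst/extdata/supplementary/ ",
         "to run this reproduction")
}
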
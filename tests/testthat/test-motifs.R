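test_that("pattern constructor enforces its gap invariants", {
  p <- cys_pattern("x", list(c(2, 4), c(0, 0)))
  expect_equal(p$cys_count, 3L)
  expect_error(cys_pattern("x", list(c(4, 2))), "min_gap")
  expect_error(cys_pattern("x", list(c(-1, 2))), ">= 0")
})

test_that("shipped patterns carry the published cysteine counts and windows", {
  p <- default_cys_patterns()
  expect_equal(vapply(p, function(x) x$cys_count, integer(1)),
               c(minus_c_obp = 4L, classic_obp = 6L, plus_c_obp = 8L,
                 csp = 4L))
  expect_equal(unname(p$minus_c_obp$gaps[, 1]), c(28, 37, 16))
  expect_equal(unname(p$minus_c_obp$gaps[, 2]), c(32, 39, 23))
  # single-width long gaps widened by 2, short gaps kept tight
  expect_equal(unname(p$csp$gaps[, 1]), c(6, 16, 2))
  expect_equal(unname(p$csp$gaps[, 2]), c(8, 20, 2))
  expect_equal(unname(p$classic_obp$gaps[2, ]), c(3L, 3L))
  p0 <- default_cys_patterns(tolerance = 0)
  expect_equal(unname(p0$csp$gaps[2, ]), c(18L, 18L))
})

test_that("the minus-C spacing example yields exactly one match", {
  # Cys at 10, 41, 80, 101: gaps 30, 38, 20 inside 28-32, 37-39, 16-23
  spacer <- function(n) strrep("A", n)
  s <- paste0(spacer(9), "C", spacer(30), "C", spacer(38), "C",
              spacer(20), "C", spacer(5))
  p <- default_cys_patterns()$minus_c_obp
  hits <- find_matches(s, p)
  expect_length(hits, 1)
  expect_equal(hits[[1]]$positions, c(10, 41, 80, 101))
  expect_equal(classify_sequence(s), "minus_c_obp")
})

test_that("the CSP spacing 7/18/2 matches the csp pattern", {
  spacer <- function(n) strrep("G", n)
  s <- paste0(spacer(3), "C", spacer(7), "C", spacer(18), "C",
              spacer(2), "C", spacer(4))
  hits <- find_matches(s, default_cys_patterns()$csp)
  expect_length(hits, 1)
  expect_equal(classify_sequence(s), "csp")
})

test_that("matching respects mature_start offsets and validates residues", {
  spacer <- function(n) strrep("A", n)
  core <- paste0("C", spacer(7), "C", spacer(18), "C", spacer(2), "C")
  s <- paste0("CCC", core)  # leading junk cysteines
  p <- default_cys_patterns()$csp
  hits <- find_matches(s, p, mature_start = 4)
  expect_length(hits, 1)
  expect_equal(hits[[1]]$positions, c(1, 9, 28, 31))
  expect_equal(hits[[1]]$offset, 3)
  expect_error(find_matches("ACDB", p), "invalid residue")
  expect_error(find_matches(s, p, mature_start = 999), "outside")
})

test_that("no-cysteine sequences and empty pattern sets are handled", {
  s <- strrep("A", 80)
  expect_length(find_matches(s, default_cys_patterns()$csp), 0)
  expect_equal(classify_sequence(s), "unclassified")
  expect_equal(classify_sequence("CACAC", patterns = list()), "unclassified")
})

test_that("every reported match verifies positions and gap windows", {
  set.seed(60)
  pats <- default_cys_patterns()
  for (i in 1:40) {
    s <- random_protein(sample(30:60, 1))
    res <- strsplit(s, "")[[1]]
    for (p in pats) {
      for (hit in find_matches(s, p)) {
        expect_true(all(res[hit$positions] == "C"))
        gaps <- diff(hit$positions) - 1
        expect_true(all(gaps >= p$gaps[, 1] & gaps <= p$gaps[, 2]))
      }
    }
  }
})

test_that("DFS matcher equals exhaustive subset enumeration", {
  set.seed(61)
  pats <- default_cys_patterns()
  for (i in 1:60) {
    s <- random_protein(sample(20:60, 1), cys_prob = 0.18)
    for (p in pats) {
      for (strict in c(FALSE, TRUE)) {
        got <- lapply(find_matches(s, p, strict = strict), `[[`, "positions")
        want <- brute_motif_matches(s, p, strict = strict)
        expect_equal(got[order(vapply(got, paste, "", collapse = ","))],
                     want[order(vapply(want, paste, "", collapse = ","))])
      }
    }
  }
})

test_that("classification prefers the pattern with more cysteines", {
  # plant a classic-OBP motif; its 6 cysteines beat any 4-cys submatch
  s <- simulate_motif_sequence(default_cys_patterns()$classic_obp, seed = 3)
  expect_equal(classify_sequence(s), "classic_obp")
  # two equal-count patterns matching -> both labels
  pats <- list(cys_pattern("a", list(c(0, 10))),
               cys_pattern("b", list(c(3, 5))))
  s2 <- "ACAAAACAA"  # two Cys, gap 4
  expect_setequal(classify_sequence(s2, pats), c("a", "b"))
})

test_that("classification ignores residues appended outside the match", {
  s <- simulate_motif_sequence(default_cys_patterns()$csp, seed = 5)
  s2 <- paste0(strrep("A", 25), s, strrep("G", 25))
  expect_equal(classify_sequence(s2), classify_sequence(s))
})

test_that("FASTA round-trips and handles wrapped records", {
  seqs <- c(p1 = strrep("ACDEFG", 25), p2 = "MKVLC")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_equal(back, seqs)
  # manually wrapped record and a multi-token header
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">idA some description", "ACDEF", "GHIKL", ">idB", "MM"), f2)
  got <- read_fasta(f2)
  expect_equal(names(got), c("idA", "idB"))
  expect_equal(unname(got[1]), "ACDEFGHIKL")
  f3 <- withr::local_tempfile(fileext = ".fasta")
  file.create(f3)
  expect_error(read_fasta(f3), "no sequences")
})

test_that("classify_fasta reports one labelled row per record", {
  pats <- default_cys_patterns()
  seqs <- c(obp = simulate_motif_sequence(pats$minus_c_obp, seed = 8),
            csp = simulate_motif_sequence(pats$csp, seed = 9),
            none = strrep("A", 50))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  tab <- classify_fasta(f)
  expect_equal(tab$id, c("obp", "csp", "none"))
  expect_equal(tab$label, c("minus_c_obp", "csp", "unclassified"))
  expect_equal(tab$n_matches, c(1L, 1L, 0L))
})
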
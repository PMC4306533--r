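toy_aln <- function() {
  seqs <- c(a1 = "MEKTDW", a2 = "MEKTDW",
            b1 = "MSKTDW", b2 = "MSKTDW")
  fams <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  labelled_alignment(seqs, fams, reference_id = "a1")
}

test_that("labelled alignments validate shape and labels", {
  expect_s3_class(toy_aln(), "labelled_alignment")
  expect_error(labelled_alignment(c(x = "ABC", y = "ABCD"),
                                  c(x = "A", y = "B")), "unequal")
  expect_error(labelled_alignment(c(x = "ABC", y = "ABC"), c(x = "A")),
               "unlabelled")
  expect_error(labelled_alignment(c(x = "ABC", y = "ABC"),
                                  c(x = "A", y = "B"), reference_id = "z"),
               "reference_id")
})

test_that("FASTA and Clustal encodings load to the identical alignment", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">a1", "MEKT-W", ">a2", "MEKTDW",
               ">b1", "MSKTDW", ">b2", "MSKTDW"), fa)
  cl <- tempfile(fileext = ".aln")
  writeLines(c("CLUSTAL W (2.1) multiple sequence alignment", "", "",
               "a1    MEKT-W", "a2    MEKTDW",
               "b1    MSKTDW", "b2    MSKTDW"), cl)
  labels <- data.frame(id = c("a1", "a2", "b1", "b2"),
                       family = c("A", "A", "B", "B"))
  from_fa <- read_alignment(fa, "fasta", labels)
  from_cl <- read_alignment(cl, "clustal", labels)
  expect_identical(from_fa, from_cl)
  expect_equal(dim(from_fa$mat), c(4L, 6L))

  # round trip through the FASTA writer
  out <- tempfile(fileext = ".fasta")
  write_alignment(from_fa, out)
  expect_identical(read_alignment(out, "fasta", labels), from_fa)

  # ragged FASTA is rejected
  bad <- tempfile(fileext = ".fasta")
  writeLines(c(">a1", "MEKTW", ">a2", "MEKTDW"), bad)
  expect_error(read_alignment(bad, "fasta", labels), ".")
})

test_that("a perfectly split column is reported with full conservation", {
  hits <- find_discriminating_positions(toy_aln())
  expect_equal(nrow(hits), 1)
  expect_equal(hits$column, 2)
  expect_equal(hits$ref_position, 2)
  expect_identical(hits$consensus_a, "E")
  expect_identical(hits$consensus_b, "S")
  expect_equal(hits$conservation_a, 1.0)
  expect_equal(hits$conservation_b, 1.0)
})

test_that("threshold and gap policy behave as documented", {
  # 8 + 8 toy with one family at 7/8 consensus in the signal column
  seqs <- c(paste0("a", 1:8), paste0("b", 1:8))
  mat <- matrix("A", nrow = 16, ncol = 4)
  mat[, 2] <- c(rep("E", 7), "Q", rep("S", 8))  # 7/8 E vs 8/8 S
  mat[, 3] <- c(rep("K", 8), rep("D", 8))       # clean split
  rows <- apply(mat, 1, paste, collapse = "")
  aln <- labelled_alignment(setNames(rows, seqs),
                            setNames(rep(c("A", "B"), each = 8), seqs))
  at85 <- find_discriminating_positions(aln, threshold = 0.85)
  at100 <- find_discriminating_positions(aln, threshold = 1.0)
  expect_setequal(at85$column, c(2, 3))
  expect_equal(at100$column, 3)
  # raising the threshold can only remove positions
  expect_true(all(at100$column %in% at85$column))
  # agreement with exhaustive enumeration
  expect_equal(at85$column, brute_discriminating_columns(aln, 0.85))
  expect_equal(at100$column, brute_discriminating_columns(aln, 1.0))

  # gapped rows: strict policy disqualifies, exclude policy ignores
  mat[1, 3] <- "-"
  rows <- apply(mat, 1, paste, collapse = "")
  aln_gap <- labelled_alignment(setNames(rows, seqs),
                                setNames(rep(c("A", "B"), each = 8), seqs))
  expect_false(3 %in% find_discriminating_positions(aln_gap, 1.0)$column)
  expect_true(3 %in% find_discriminating_positions(aln_gap, 1.0,
                                                   gap_policy = "exclude")$column)

  expect_error(find_discriminating_positions(aln, threshold = 0.4),
               "threshold")
})

test_that("discrimination scan equals brute force on random alignments", {
  for (s in 1:8) {
    sim <- simulate_labelled_alignment(n_a = 6, n_b = 6, n_col = 150,
                                       n_planted = 10, sub_rate = 0.12,
                                       gap_rate = 0.03, seed = 800 + s)
    for (thr in c(0.85, 1.0)) {
      for (gp in c("strict", "exclude")) {
        got <- find_discriminating_positions(sim$aln, thr, gap_policy = gp)
        want <- brute_discriminating_columns(sim$aln, thr, gp)
        expect_equal(got$column, want,
                     info = sprintf("seed %d thr %.2f %s", s, thr, gp))
      }
    }
    # planted columns are always recovered under the strict scan
    strict <- find_discriminating_positions(sim$aln, 1.0)
    expect_true(all(sim$planted_columns %in% strict$column))
  }
})

test_that("functional-site annotation tags nearby discriminating positions", {
  ann <- site_annotations()
  expect_true(all(c("W56", "W102", "E103", "W166") %in% names(ann)))
  expect_equal(unname(ann["W102"]), 102L)

  sim <- simulate_labelled_alignment(n_col = 120, n_planted = 6, seed = 3)
  hits <- find_discriminating_positions(sim$aln, 1.0,
                                        annotation = c(X10 = 10L),
                                        annotation_window = 2L)
  near <- !is.na(hits$near_site)
  expect_equal(near, abs(hits$ref_position - 10L) <= 2L)
})

test_that("N-terminal charge counts basic minus acidic residues", {
  expect_equal(nterm_charge("KKRK", window = 4), 4L)
  expect_equal(nterm_charge("DDEE", window = 4), -4L)
  expect_equal(nterm_charge("MKKRDE", window = 6), 1L)
  expect_equal(nterm_charge("AAAA", window = 0), 0L)
  expect_equal(nterm_charge("HHHH", window = 4), 0L)
  expect_equal(nterm_charge("HHHH", window = 4, his_charge = 1), 4L)
  expect_error(nterm_charge("MK-RDE", window = 6), "non-residue")
  expect_error(nterm_charge("MK", window = 5), "window")
  # window charges tile: prefix charge is the sum over tiling windows
  s <- "MKKRDEDKRE"
  expect_equal(nterm_charge(s, 10),
               nterm_charge(substr(s, 1, 5), 5) +
                 nterm_charge(substr(s, 6, 10), 5))
})

test_that("numbering maps by constant offsets with a bundled table", {
  expect_equal(map_numbering(98, 4), 102L)
  expect_equal(map_numbering(c(206, 207), 4), c(210L, 211L))
  expect_equal(map_numbering(57, 0), 57L)
  expect_error(map_numbering(2, -5), "below 1")

  off <- numbering_offsets()
  x2h <- off$offset[off$from_protein == "XeIF4E1a" &
                    off$to_protein == "heIF4E1a"]
  expect_equal(x2h, 4L)
  expect_equal(off$offset[off$from_protein == "heIF4E1a" &
                          off$to_protein == "XeIF4E1b"], 0L)
  # offsets are mutually inverse
  for (i in seq_len(nrow(off))) {
    inv <- off$offset[off$from_protein == off$to_protein[i] &
                      off$to_protein == off$from_protein[i]]
    expect_equal(off$offset[i], -inv)
  }
})
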
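test_that("degenerate base matching follows IUPAC semantics", {
  expect_true(iupac_match("N", "A"))
  expect_true(iupac_match("N", "N"))
  expect_true(iupac_match("R", "G"))
  expect_true(iupac_match("R", "A"))
  expect_false(iupac_match("R", "C"))
  expect_false(iupac_match("A", "N"))  # unknown base is never a concrete base
  expect_true(iupac_match("A", "A"))
  expect_error(iupac_match("X", "A"), "invalid IUPAC")
  expect_error(iupac_match("A", "R"), "invalid genome")
})

test_that("reverse complement handles degenerate bases and is an involution", {
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("NRG"), "CYN")
  expect_identical(reverse_complement("TTTN"), "NAAA")
  expect_error(reverse_complement("ACX"), "invalid IUPAC")

  set.seed(11)
  alphabet <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V", "N")
  for (i in 1:25) {
    s <- paste(sample(alphabet, sample(1:40, 1), replace = TRUE),
               collapse = "")
    expect_identical(reverse_complement(reverse_complement(s)), s)
    # independent cross-check against Biostrings' complement table
    expect_identical(
      reverse_complement(s),
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(s))))
  }
})

test_that("pattern compilation concatenates spacer and PAM by orientation", {
  q3 <- guide_query("ACGTACGT", nrg(), 0)
  c3 <- compile_pattern(q3)
  expect_identical(c3$pattern, "ACGTACGTNRG")
  expect_identical(c3$length, 11L)
  expect_identical(c3$spacer_mask, c(rep(TRUE, 8), rep(FALSE, 3)))

  q5 <- guide_query("ACGTACGT", tttn(), 0)
  c5 <- compile_pattern(q5)
  expect_identical(c5$pattern, "TTTNACGTACGT")
  expect_identical(c5$length, 12L)
  expect_identical(c5$spacer_mask, c(rep(FALSE, 4), rep(TRUE, 8)))

  expect_error(guide_query("", nrg(), 0), "non-empty")
})

test_that("mismatch counting separates spacer budget from the PAM gate", {
  compiled <- compile_pattern(guide_query("ACGTACGT", nrg(), 2))
  exact <- count_mismatches(compiled, "ACGTACGTAGG")
  expect_identical(exact$spacer_mismatches, 0L)
  expect_true(exact$pam_ok)

  one <- count_mismatches(compiled, "ACGAACGTAGG")  # T->A at spacer pos 3
  expect_identical(one$spacer_mismatches, 1L)
  expect_true(one$pam_ok)

  pam_fail <- count_mismatches(compiled, "ACGTACGTACC")
  expect_identical(pam_fail$spacer_mismatches, 0L)
  expect_false(pam_fail$pam_ok)

  expect_error(count_mismatches(compiled, "ACGT"), "length")
})

test_that("scanning finds planted sites on both strands", {
  q <- guide_query("ACGTACGT", nrg(), 0, id = "g1")
  seq_plus <- paste0(strrep("T", 20), "ACGTACGTAGG", strrep("T", 20))
  h <- scan_sequence("chr1", seq_plus, q)
  expect_identical(nrow(h), 1L)
  expect_identical(h$position, 20L)
  expect_identical(h$strand, "+")
  expect_identical(h$mismatches, 0L)
  expect_identical(h$matched_seq, "ACGTACGTAGG")

  seq_minus <- paste0(strrep("T", 20), reverse_complement("ACGTACGTAGG"),
                      strrep("T", 20))
  hm <- scan_sequence("chr1", seq_minus, q)
  expect_identical(nrow(hm), 1L)
  expect_identical(hm$strand, "-")
  expect_identical(hm$position, 20L)
  expect_identical(hm$matched_seq, "ACGTACGTAGG")

  expect_identical(nrow(scan_sequence("chr1", "", q)), 0L)
})

test_that("mismatched spacer bases are lowercased in matched_seq", {
  q <- guide_query("ACGTACGT", nrg(), 1, id = "g1")
  s <- paste0(strrep("C", 10), "ACGAACGTTGG", strrep("C", 10))
  h <- scan_sequence("chr1", s, q)
  expect_identical(h$matched_seq[h$strand == "+"], "ACGaACGTTGG")
  # same site on the minus strand
  s2 <- paste0(strrep("C", 10), reverse_complement("ACGAACGTTGG"),
               strrep("C", 10))
  h2 <- scan_sequence("chr1", s2, q)
  expect_identical(h2$matched_seq[h2$strand == "-"], "ACGaACGTTGG")
})

test_that("scanner agrees with the brute-force oracle on random instances", {
  set.seed(101)
  pams <- list(nrg(), ngg(), tttn())
  for (i in 1:30) {
    L <- sample(300:1200, 1)
    seqs <- random_dna(L)
    spacer <- random_dna(sample(15:25, 1))
    k <- sample(0:4, 1)
    q <- guide_query(spacer, pams[[sample(3, 1)]], k, id = "q")
    fast <- scan_sequence("t", seqs, q)
    slow <- brute_force_scan("t", seqs, q)
    expect_identical(fast, slow)
  }
})

test_that("hits are monotone in the mismatch budget", {
  set.seed(55)
  s <- random_dna(2000)
  spacer <- random_dna(18)
  for (k in 0:3) {
    hk <- scan_sequence("t", s, guide_query(spacer, nrg(), k))
    hk1 <- scan_sequence("t", s, guide_query(spacer, nrg(), k + 1))
    key <- function(h) paste(h$position, h$strand)
    expect_true(all(key(hk) %in% key(hk1)))
  }
})

test_that("scanning is strand-symmetric and deterministic", {
  set.seed(77)
  for (i in 1:5) {
    s <- random_dna(800)
    q <- guide_query(random_dna(20), nrg(), 2, id = "q")
    m <- nchar(q$spacer) + nchar(q$pam$pattern)
    h <- scan_sequence("t", s, q)
    hrc <- scan_sequence("t", reverse_complement(s), q)
    # mirror: a + hit at p in s is a - hit at L - m - p in revcomp(s)
    mirrored <- data.frame(position = nchar(s) - m - hrc$position,
                           strand = chartr("+-", "-+", hrc$strand),
                           mismatches = hrc$mismatches,
                           stringsAsFactors = FALSE)
    mirrored <- mirrored[order(mirrored$position, mirrored$strand), ]
    expect_identical(h$position, mirrored$position)
    expect_identical(h$strand, mirrored$strand)
    expect_identical(h$mismatches, mirrored$mismatches)
    expect_identical(h, scan_sequence("t", s, q))
  }
})

test_that("genome N windows fail concrete pattern positions", {
  q <- guide_query("ACGTACGT", nrg(), 0, id = "g")
  s <- paste0(strrep("T", 10), "ACGNACGTAGG", strrep("T", 10))
  expect_identical(nrow(scan_sequence("c", s, q)), 0L)  # N is a mismatch
  q1 <- guide_query("ACGTACGT", nrg(), 1, id = "g")
  expect_identical(nrow(scan_sequence("c", s, q1)), 1L)
  # N in the PAM is a PAM failure at any budget
  s2 <- paste0(strrep("T", 10), "ACGTACGTANG", strrep("T", 10))
  expect_identical(nrow(scan_sequence("c", s2, q1)), 0L)
})

test_that("hit TSVs round-trip through write and read", {
  q <- guide_query("ACGTACGT", nrg(), 1, id = "g1")
  set.seed(3)
  s <- paste0(random_dna(50), "ACGTACGTAGG", random_dna(50))
  h <- scan_sequence("chr1", s, q)
  p <- tempfile(fileext = ".tsv")
  write_hits_tsv(h, p)
  back <- read_hits_tsv(p)
  expect_identical(back$position, h$position)
  expect_identical(back$matched_seq, h$matched_seq)
  expect_true(all(is.na(back$ref_position)))
  # 1-based dialect converts back to the same internal coordinates
  write_hits_tsv(h, p, one_based = TRUE)
  expect_identical(read_hits_tsv(p)$position, h$position)
})
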
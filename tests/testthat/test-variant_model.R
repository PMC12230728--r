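test_that("a phased single-sample VCF parses to records and genotypes", {
  p <- write_test_vcf("chr1\t5\t.\tA\tG\t.\t.\t.\tGT\t0|1")
  parsed <- parse_vcf(p)
  expect_identical(length(parsed$records), 1L)
  r <- parsed$records[[1]]
  expect_identical(r$chrom, "chr1")
  expect_identical(r$pos, 4L)  # 0-based internally
  expect_identical(r$ref, "A")
  expect_identical(r$alts, "G")
  expect_identical(r$gt$indices, c(0L, 1L))
  expect_true(r$gt$phased)
  expect_identical(parsed$ploidy, 2L)
})

test_that("unphased, missing and multi-sample genotypes are handled", {
  p <- write_test_vcf("chr1\t5\t.\tA\tG\t.\t.\t.\tGT\t1/1")
  expect_error(parse_vcf(p), "unphased")
  expect_identical(length(parse_vcf(p, assume_phased = TRUE)$records), 1L)

  p2 <- write_test_vcf(c("chr1\t5\t.\tA\tG\t.\t.\t.\tGT\t.",
                         "chr1\t50\t.\tC\tT\t.\t.\t.\tGT\t0|1"))
  expect_warning(parsed <- parse_vcf(p2), "missing genotype")
  expect_identical(length(parsed$records), 1L)
  expect_identical(parsed$warnings[["missing_genotype"]], 1L)

  p3 <- write_test_vcf("chr1\t5\t.\tA\tG\t.\t.\t.\tGT\t0|1\t0|0",
                       samples = c("s1", "s2"))
  expect_error(parse_vcf(p3), "s1, s2")
  expect_identical(length(parse_vcf(p3, sample = "s2")$records), 1L)

  # homozygous-reference record is retained but contributes no variant
  p4 <- write_test_vcf("chr1\t5\t.\tA\tG\t.\t.\t.\tGT\t0|0")
  parsed4 <- parse_vcf(p4)
  expect_identical(length(parsed4$records), 1L)
  assigned <- split_multiallelic(parsed4$records[[1]])
  expect_identical(lengths(assigned), c(0L, 0L))
})

test_that("ploidy changes and out-of-range genotype indices are errors", {
  p <- write_test_vcf(c("chr1\t5\t.\tA\tG\t.\t.\t.\tGT\t0|1",
                        "chr1\t50\t.\tC\tT\t.\t.\t.\tGT\t0|1|1"))
  expect_error(parse_vcf(p), "ploidy")
  p2 <- write_test_vcf("chr1\t5\t.\tA\tG\t.\t.\t.\tGT\t0|2")
  expect_error(parse_vcf(p2), "exceeds ALT count")
})

test_that("FILTER handling: permissive by default, PASS-only on request", {
  body <- c("chr1\t5\t.\tA\tG\t.\tq10\t.\tGT\t0|1",
            "chr1\t50\t.\tC\tT\t.\tPASS\t.\tGT\t0|1")
  p <- write_test_vcf(body)
  expect_identical(length(parse_vcf(p)$records), 2L)
  kept <- parse_vcf(p, pass_only = TRUE)
  expect_identical(length(kept$records), 1L)
  expect_identical(kept$records[[1]]$pos, 49L)
})

test_that("complex substitutions decompose into SNV primitives plus one indel", {
  # equal length: positional diff only
  prims <- decompose_primitives(list(chrom = "c", pos = 10L, ref = "CAT",
                                     alts = "GAC", line = 1L))
  expect_identical(length(prims), 2L)
  expect_identical(prims[[1]]$pos, 10L)
  expect_identical(prims[[1]]$ref, "C"); expect_identical(prims[[1]]$alt, "G")
  expect_identical(prims[[2]]$pos, 12L)
  expect_identical(prims[[2]]$ref, "T"); expect_identical(prims[[2]]$alt, "C")

  # already-primitive deletion passes through
  del <- decompose_primitives(list(chrom = "c", pos = 3L, ref = "ATG",
                                   alts = "A", line = 2L))
  expect_identical(length(del), 1L)
  expect_identical(del[[1]]$ref, "ATG")
  expect_identical(del[[1]]$alt, "A")

  # end-anchored trim: verified against an independent suffix/prefix trim
  tr <- decompose_primitives(list(chrom = "c", pos = 7L, ref = "ACGT",
                                  alts = "AT", line = 3L))
  expect_identical(length(tr), 1L)
  expect_identical(tr[[1]]$pos, 7L)
  expect_identical(tr[[1]]$ref, "ACG")
  expect_identical(tr[[1]]$alt, "A")

  expect_warning(
    none <- decompose_primitives(list(chrom = "c", pos = 1L, ref = "A",
                                      alts = "<DEL>", line = 4L)),
    "symbolic")
  expect_identical(length(none), 0L)
})

test_that("decomposition is idempotent and sequence-preserving", {
  set.seed(21)
  for (i in 1:50) {
    s <- random_dna(60)
    pos <- sample(5:30, 1)
    lr <- sample(1:6, 1); la <- sample(1:6, 1)
    ref <- substr(s, pos + 1, pos + lr)
    alt <- random_dna(la)
    if (alt == ref) next
    rec <- list(chrom = "c", pos = pos, ref = ref, alts = alt, line = i)
    prims <- decompose_primitives(rec)
    # idempotence: re-decomposing every primitive returns it unchanged
    for (pr in prims) {
      again <- decompose_primitives(pr)
      expect_identical(length(again), 1L)
      expect_identical(again[[1]]$pos, pr$pos)
      expect_identical(again[[1]]$ref, pr$ref)
      expect_identical(again[[1]]$alt, pr$alt)
    }
    # applying all primitives reproduces applying the original record
    df <- data.frame(chrom = "c",
                     pos = vapply(prims, `[[`, 0L, "pos"),
                     ref = vapply(prims, `[[`, "", "ref"),
                     alt = vapply(prims, `[[`, "", "alt"))
    df <- df[order(df$pos), , drop = FALSE]
    expect_identical(splice_oracle(s, df),
                     apply_variant_str(s, pos, ref, alt))
  }
})

test_that("multiallelic records split by genotype index", {
  rec <- list(chrom = "c", pos = 10L, ref = "A", alts = c("C", "T"),
              line = 1L)
  a12 <- split_multiallelic(rec, list(indices = c(1L, 2L), phased = TRUE))
  expect_identical(a12[[1]][[1]]$alt, "C")
  expect_identical(a12[[2]][[1]]$alt, "T")

  a02 <- split_multiallelic(rec, list(indices = c(0L, 2L), phased = TRUE))
  expect_identical(length(a02[[1]]), 0L)
  expect_identical(a02[[2]][[1]]$alt, "T")

  hom <- split_multiallelic(list(chrom = "c", pos = 10L, ref = "A",
                                 alts = "G", line = 2L),
                            list(indices = c(1L, 1L), phased = TRUE))
  expect_identical(hom[[1]][[1]]$alt, "G")
  expect_identical(hom[[2]][[1]]$alt, "G")

  expect_error(
    split_multiallelic(rec, list(indices = c(0L, 3L), phased = TRUE)),
    "exceeds ALT count")

  # allele-content conservation: the union of assignments is the genotype
  gt <- list(indices = c(2L, 1L), phased = TRUE)
  parts <- split_multiallelic(rec, gt)
  got <- vapply(seq_along(parts), function(h)
    if (length(parts[[h]])) parts[[h]][[1]]$alt else "", "")
  expect_identical(got, c("T", "C"))
})

test_that("left alignment matches the spec examples and leaves SNVs fixed", {
  ref <- c(chr = "AATTTTC")
  snv <- variant_record("chr", 4L, "T", "G")
  expect_identical(normalize_left_align(snv, ref)$pos, 4L)
  expect_identical(normalize_left_align(snv, ref)$ref, "T")

  v <- variant_record("chr", 3L, "TT", "T")
  nv <- normalize_left_align(v, ref)
  expect_identical(nv$pos, 1L)
  expect_identical(nv$ref, "AT")
  expect_identical(nv$alt, "A")

  expect_error(normalize_left_align(variant_record("chr", 90L, "T", "G"), ref),
               "outside chromosome")
  expect_error(normalize_left_align(variant_record("chr", 2L, "AA", "A"), ref),
               "reference mismatch")
})

test_that("left alignment agrees with the exhaustive shift oracle and is idempotent", {
  set.seed(33)
  for (i in 1:120) {
    s <- random_dna(80, repeat_rich = TRUE)
    v <- random_indel(s)
    nv <- normalize_left_align(v, s)
    o <- normalize_oracle(v, s)
    expect_identical(nv$pos, o$pos)
    expect_identical(nv$ref, o$ref)
    expect_identical(nv$alt, o$alt)
    # idempotence
    nv2 <- normalize_left_align(nv, s)
    expect_identical(nv2[c("pos", "ref", "alt")], nv[c("pos", "ref", "alt")])
    # sequence equivalence preserved by normalization
    expect_identical(apply_variant_str(s, nv$pos, nv$ref, nv$alt),
                     apply_variant_str(s, v$pos, v$ref, v$alt))
  }
})

test_that("haplotype sets are sorted, per-haplotype, and overlap-checked", {
  # het SNP 0|1: set 1 empty, set 2 has the variant
  per_hap <- list(list(), list(variant_record("chr1", 5L, "A", "G", 10L)))
  sets <- build_haplotype_sets(per_hap)
  expect_identical(nrow(sets[[1]]), 0L)
  expect_identical(nrow(sets[[2]]), 1L)
  expect_identical(attr(sets[[2]], "label"), "allele2")

  # overlapping deletions in strict mode
  ov <- list(list(variant_record("chr1", 5L, "ACG", "A", 3L),
                  variant_record("chr1", 6L, "CGT", "C", 7L)))
  expect_error(build_haplotype_sets(ov), "lines 3 and 7")
  expect_warning(lax <- build_haplotype_sets(ov, strict = FALSE), "skipped")
  expect_identical(nrow(lax[[1]]), 1L)

  # triploid 0|1|1: three sets, sets 2 and 3 identical
  v <- variant_record("chr1", 5L, "A", "G", 2L)
  tri <- build_haplotype_sets(list(list(), list(v), list(v)))
  expect_identical(length(tri), 3L)
  expect_identical(tri[[2]]$alt, tri[[3]]$alt)
  expect_identical(nrow(tri[[1]]), 0L)
})

test_that("the VCF-to-sets pipeline yields reference-matching variants", {
  set.seed(44)
  genome <- generate_genome(2, 800)
  vcf <- generate_phased_vcf(genome, tempfile(fileext = ".vcf"),
                             n_snps = 5, n_insertions = 2, n_deletions = 2,
                             n_mnps = 2, n_multiallelic = 1)
  hs <- vcf_haplotype_sets(vcf$path, genome)
  expect_identical(hs$ploidy, 2L)
  for (set in hs$sets) {
    for (i in seq_len(nrow(set))) {
      obs <- substr(genome[[set$chrom[i]]], set$pos[i] + 1,
                    set$pos[i] + nchar(set$ref[i]))
      expect_identical(obs, set$ref[i])
    }
    if (nrow(set) > 1)
      expect_true(all(diff(order(set$chrom, set$pos)) == 1))
  }
})
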
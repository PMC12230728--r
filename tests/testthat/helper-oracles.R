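# Independent oracles and small fixture builders shared by the tests.
# These deliberately use different algorithms from the package internals:
# character-level edit replay instead of block splicing, exhaustive
# enumeration instead of iterative shifting.

# Apply a single variant (0-based pos, ref span replaced by alt) to a
# sequence by direct string surgery.
apply_variant_str <- function(s, pos, ref, alt) {
  stopifnot(substr(s, pos + 1L, pos + nchar(ref)) == ref)
  paste0(substr(s, 1L, pos), alt, substr(s, pos + nchar(ref) + 1L, nchar(s)))
}

# Rebuild a haplotype by replaying edits right-to-left, one substitution at
# a time (independent of the package's left-to-right block splice).
splice_oracle <- function(ref_seq, variants) {
  if (!nrow(variants)) return(ref_seq)
  v <- variants[order(-variants$pos), , drop = FALSE]
  s <- ref_seq
  for (i in seq_len(nrow(v)))
    s <- apply_variant_str(s, v$pos[i], v$ref[i], v$alt[i])
  s
}

# Exhaustive left-shift oracle for a pure indel: enumerate every anchored
# single-indel representation, keep those whose application reproduces the
# same edited sequence, return the leftmost.
normalize_oracle <- function(v, ref_seq) {
  target <- apply_variant_str(ref_seq, v$pos, v$ref, v$alt)
  L <- nchar(ref_seq)
  d <- nchar(v$ref) - nchar(v$alt)
  stopifnot(d != 0L)
  if (d > 0L) {
    for (p in 0:(L - d - 1L)) {
      r <- substr(ref_seq, p + 1L, p + 1L + d)
      a <- substr(r, 1L, 1L)
      if (nchar(r) == d + 1L &&
          apply_variant_str(ref_seq, p, r, a) == target)
        return(list(pos = p, ref = r, alt = a))
    }
  } else {
    ins_len <- -d
    for (p in 0:(L - 1L)) {
      r <- substr(ref_seq, p + 1L, p + 1L)
      ins <- substr(target, p + 2L, p + 1L + ins_len)
      a <- paste0(r, ins)
      if (nchar(ins) == ins_len &&
          apply_variant_str(ref_seq, p, r, a) == target)
        return(list(pos = p, ref = r, alt = a))
    }
  }
  stop("oracle found no representation")
}

# Random DNA, optionally repeat-rich (short alphabet runs make indels
# shiftable, stressing left-alignment).
random_dna <- function(n, repeat_rich = FALSE) {
  if (repeat_rich) {
    out <- character(0)
    while (sum(nchar(out)) < n) {
      unit <- paste(sample(c("A", "C", "G", "T"),
                           sample(1:3, 1L), replace = TRUE), collapse = "")
      out <- c(out, strrep(unit, sample(1:6, 1L)))
    }
    substr(paste(out, collapse = ""), 1L, n)
  } else {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }
}

# A random pure indel (deletion or insertion) on `ref_seq`, as a
# variant_record, guaranteed valid against the sequence.
random_indel <- function(ref_seq, max_len = 8L) {
  L <- nchar(ref_seq)
  len <- sample.int(max_len, 1L)
  if (stats::runif(1) < 0.5) {
    pos <- sample.int(L - len - 2L, 1L)
    variant_record("chr", pos,
                   substr(ref_seq, pos + 1L, pos + 1L + len),
                   substr(ref_seq, pos + 1L, pos + 1L), line = 1L)
  } else {
    pos <- sample.int(L - 2L, 1L)
    anchor <- substr(ref_seq, pos + 1L, pos + 1L)
    ins <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
    variant_record("chr", pos, anchor, paste0(anchor, ins), line = 1L)
  }
}

# A sorted non-overlapping random variant set (SNVs + indels) on a
# sequence, spaced so normalization shifts cannot collide.
random_variant_set <- function(ref_seq, n, max_indel = 8L, gap = 25L) {
  L <- nchar(ref_seq)
  rows <- list()
  cursor <- 5L
  for (i in seq_len(n)) {
    cursor <- cursor + sample(gap:(gap + 40L), 1L)
    if (cursor + max_indel + 10L >= L) break
    kind <- sample(c("snv", "del", "ins"), 1L)
    if (kind == "snv") {
      refb <- substr(ref_seq, cursor + 1L, cursor + 1L)
      altb <- sample(setdiff(c("A", "C", "G", "T"), refb), 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = "chr", pos = cursor, ref = refb, alt = altb, line = i)
      cursor <- cursor + 1L
    } else if (kind == "del") {
      d <- sample.int(max_indel, 1L)
      ref <- substr(ref_seq, cursor + 1L, cursor + 1L + d)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = "chr", pos = cursor, ref = ref, alt = substr(ref, 1L, 1L),
        line = i)
      cursor <- cursor + d + 1L
    } else {
      d <- sample.int(max_indel, 1L)
      anchor <- substr(ref_seq, cursor + 1L, cursor + 1L)
      ins <- paste(sample(c("A", "C", "G", "T"), d, replace = TRUE),
                   collapse = "")
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = "chr", pos = cursor, ref = anchor,
        alt = paste0(anchor, ins), line = i)
      cursor <- cursor + 1L
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), line = integer(0))
  attr(df, "label") <- "allele1"
  df
}

# Write a minimal VCF from record strings (body lines), for parser tests.
write_test_vcf <- function(body, path = tempfile(fileext = ".vcf"),
                           samples = "s1",
                           contigs = c(chr1 = 1000L)) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body), path)
  path
}

nrg <- function() pam_spec("NRG", "NRG", "three_prime")
ngg <- function() pam_spec("NGG", "NGG", "three_prime")
tttn <- function() pam_spec("TTTN", "TTTN", "five_prime")
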
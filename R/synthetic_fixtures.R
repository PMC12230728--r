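# Seeded synthetic genomes, phased VCFs and planted gain/loss off-target
# sites, so the whole pipeline is testable without any external data; also
# houses the brute-force scan oracle used in tests.
#
# All randomness flows from one seed set at the entry point of each
# generator; no wall-clock or OS entropy. Identical specs give byte-identical
# files.

.concrete_base <- function(pattern_char) {
  # a concrete ACGT base satisfying the IUPAC char (uniform over its set)
  set <- setdiff(.IUPAC_SETS[[pattern_char]], "N")
  set[sample.int(length(set), 1L)]
}

.mismatch_base <- function(pattern_char) {
  # a concrete base NOT satisfying the IUPAC char; NULL if impossible
  bad <- setdiff(c("A", "C", "G", "T"), .IUPAC_SETS[[pattern_char]])
  if (!length(bad)) return(NULL)
  bad[sample.int(length(bad), 1L)]
}

#' Generate a reproducible random genome
#'
#' @param n_chroms Number of chromosomes (named `chr1`, `chr2`, ...).
#' @param chrom_length Length of each chromosome (>= 200).
#' @param gc_fraction Target GC content.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return Named character vector of uppercase DNA sequences.
#' @export
generate_genome <- function(n_chroms = 2L, chrom_length = 5000L,
                            gc_fraction = 0.41, seed = NULL) {
  if (n_chroms < 1L || any(chrom_length < 200L))
    stop("degenerate fixture spec: need >= 1 chromosome of >= 200 bp")
  if (gc_fraction <= 0 || gc_fraction >= 1)
    stop("gc_fraction must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  lens <- rep_len(chrom_length, n_chroms)
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seqs <- vapply(lens, function(L) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, "")
  names(seqs) <- paste0("chr", seq_len(n_chroms))
  seqs
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

# Realize a guide pattern as a concrete genomic window in guide frame,
# with exactly `mismatches` spacer mismatches. Returns list(guide_frame,
# genomic = forward-strand string to write at the site).
.realize_window <- function(q, mismatches = 0L, strand = "+") {
  compiled <- compile_pattern(q)
  chars <- compiled$chars
  win <- vapply(chars, .concrete_base, "")
  sp_idx <- which(compiled$spacer_mask)
  can_mm <- sp_idx[chars[sp_idx] != "N"]
  if (mismatches > nchar(q$spacer))
    stop("requested mismatches exceed spacer length")
  if (mismatches > length(can_mm))
    stop("spacer has too few constrained positions for ", mismatches,
         " mismatches")
  if (mismatches > 0L) {
    at <- sample(can_mm, mismatches)
    for (j in at) win[j] <- .mismatch_base(chars[j])
  }
  gf <- paste(win, collapse = "")
  list(guide_frame = gf,
       genomic = if (strand == "+") gf else reverse_complement(gf))
}

#' Plant an off-target site into a genome
#'
#' Overwrites a window of the chosen chromosome with a concrete sequence
#' matching the query at exactly the requested spacer mismatch count, on the
#' requested strand, and records the ground truth.
#'
#' @param genome Named character vector of sequences.
#' @param chrom Chromosome name.
#' @param pos 0-based start of the planted window (must leave at least one
#'   pattern length of margin to each chromosome edge).
#' @param query A [guide_query()].
#' @param mismatches Exact spacer mismatch count to plant.
#' @param strand `"+"` or `"-"`.
#' @return List with `genome` (modified) and `truth` (one-row data.frame:
#'   `chrom`, `pos`, `strand`, `mismatches`, `seq`).
#' @export
plant_site <- function(genome, chrom, pos, query, mismatches = 0L,
                       strand = "+") {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  m <- nchar(query$spacer) + nchar(query$pam$pattern)
  L <- nchar(genome[[chrom]])
  if (pos < m || pos + 2L * m > L)
    stop("planted site too close to chromosome edge")
  r <- .realize_window(query, mismatches, strand)
  s <- genome[[chrom]]
  genome[[chrom]] <- paste0(substr(s, 1L, pos), r$genomic,
                            substr(s, pos + m + 1L, L))
  stopifnot(nchar(genome[[chrom]]) == L)
  list(genome = genome,
       truth = data.frame(chrom = chrom, pos = as.integer(pos),
                          strand = strand,
                          mismatches = as.integer(mismatches),
                          seq = r$genomic, stringsAsFactors = FALSE))
}

.overlaps_any <- function(intervals, chrom, start, end) {
  if (!length(intervals)) return(FALSE)
  any(vapply(intervals, function(iv) {
    iv$chrom == chrom && start < iv$end && end > iv$start
  }, logical(1)))
}

.random_gt <- function(ploidy, n_alt) {
  repeat {
    idx <- sample(0:n_alt, ploidy, replace = TRUE)
    if (any(idx > 0L)) return(idx)
  }
}

.gt_string <- function(idx) paste(idx, collapse = "|")

.write_vcf <- function(records, genome, path, sample_name = "sample1") {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(genome), nchar(genome)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_name)
  )
  body <- character(0)
  if (length(records)) {
    df <- do.call(rbind, records)
    df <- df[order(match(df$chrom, names(genome)), df$pos1), , drop = FALSE]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.\tGT\t%s",
                    df$chrom, df$pos1, df$ref, df$alt, df$gt)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Generate a phased synthetic VCF over a genome
#'
#' Draws non-overlapping SNPs, insertions, deletions, MNPs and multiallelic
#' SNV records with phased genotypes at the requested ploidy, writes a valid
#' sorted VCF 4.2, and returns the per-haplotype ground-truth edits.
#' Variants are kept well apart (and out of `avoid` intervals) so that
#' left-alignment cannot make independent records collide.
#'
#' @param genome Named character vector of sequences.
#' @param path Output VCF path.
#' @param n_snps,n_insertions,n_deletions,n_mnps,n_multiallelic Record counts.
#' @param ploidy Number of haplotypes (>= 1).
#' @param indel_range Length range (bases inserted/deleted) for indels.
#' @param avoid List of reserved intervals `list(chrom=, start=, end=)` that
#'   variants must not touch.
#' @param extra Optional list of pre-built record data.frames (columns
#'   `chrom`, `pos1`, `ref`, `alt`, `gt`) merged into the output.
#' @param sample_name VCF sample column name.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return List with `path` and `truth`: data.frame of applied edits per
#'   haplotype (`chrom`, `pos` 0-based, `ref`, `alt`, `hap`).
#' @export
generate_phased_vcf <- function(genome, path, n_snps = 10L,
                                n_insertions = 3L, n_deletions = 3L,
                                n_mnps = 2L, n_multiallelic = 1L,
                                ploidy = 2L, indel_range = c(1L, 10L),
                                avoid = list(), extra = list(),
                                sample_name = "sample1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (ploidy < 1L) stop("ploidy must be >= 1")
  pad <- 30L  # spacing so normalization shifts cannot cause overlap
  occupied <- avoid
  records <- extra
  truth <- list()
  bases <- c("A", "C", "G", "T")

  pick_pos <- function(span) {
    # returns list(chrom, pos0) with [pos0-pad, pos0+span+pad) free
    for (try in 1:500) {
      chrom <- names(genome)[sample.int(length(genome), 1L)]
      L <- nchar(genome[[chrom]])
      if (L < span + 2L * pad + 20L) next
      pos0 <- sample.int(L - span - 2L * pad - 10L, 1L) + pad
      if (!.overlaps_any(occupied, chrom, pos0 - pad, pos0 + span + pad)) {
        occupied[[length(occupied) + 1L]] <<-
          list(chrom = chrom, start = pos0 - pad, end = pos0 + span + pad)
        return(list(chrom = chrom, pos0 = pos0))
      }
    }
    stop("infeasible variant density: could not place variant")
  }

  add_record <- function(chrom, pos0, ref, alt_vec, gt_idx) {
    records[[length(records) + 1L]] <<- data.frame(
      chrom = chrom, pos1 = pos0 + 1L, ref = ref,
      alt = paste(alt_vec, collapse = ","), gt = .gt_string(gt_idx),
      stringsAsFactors = FALSE)
    for (h in seq_len(ploidy)) {
      g <- gt_idx[h]
      if (g > 0L)
        truth[[length(truth) + 1L]] <<- data.frame(
          chrom = chrom, pos = pos0, ref = ref, alt = alt_vec[g], hap = h,
          stringsAsFactors = FALSE)
    }
  }

  for (i in seq_len(n_snps)) {
    loc <- pick_pos(1L)
    refb <- substr(genome[[loc$chrom]], loc$pos0 + 1L, loc$pos0 + 1L)
    altb <- sample(setdiff(bases, refb), 1L)
    add_record(loc$chrom, loc$pos0, refb, altb, .random_gt(ploidy, 1L))
  }
  for (i in seq_len(n_insertions)) {
    len <- sample(indel_range[1]:indel_range[2], 1L)
    loc <- pick_pos(1L)
    anchor <- substr(genome[[loc$chrom]], loc$pos0 + 1L, loc$pos0 + 1L)
    ins <- paste(sample(bases, len, replace = TRUE), collapse = "")
    add_record(loc$chrom, loc$pos0, anchor, paste0(anchor, ins),
               .random_gt(ploidy, 1L))
  }
  for (i in seq_len(n_deletions)) {
    len <- sample(indel_range[1]:indel_range[2], 1L)
    loc <- pick_pos(len + 1L)
    ref <- substr(genome[[loc$chrom]], loc$pos0 + 1L, loc$pos0 + 1L + len)
    add_record(loc$chrom, loc$pos0, ref, substr(ref, 1L, 1L),
               .random_gt(ploidy, 1L))
  }
  for (i in seq_len(n_mnps)) {
    len <- sample(2:3, 1L)
    loc <- pick_pos(len)
    ref <- substr(genome[[loc$chrom]], loc$pos0 + 1L, loc$pos0 + len)
    rch <- strsplit(ref, "")[[1L]]
    ach <- vapply(rch, function(b) sample(setdiff(bases, b), 1L), "")
    add_record(loc$chrom, loc$pos0, ref, paste(ach, collapse = ""),
               .random_gt(ploidy, 1L))
  }
  for (i in seq_len(n_multiallelic)) {
    loc <- pick_pos(1L)
    refb <- substr(genome[[loc$chrom]], loc$pos0 + 1L, loc$pos0 + 1L)
    alts <- sample(setdiff(bases, refb), 2L)
    # force both alternates to be used when ploidy allows
    gt_idx <- if (ploidy >= 2L) {
      c(1L, 2L, sample(0:2, max(0L, ploidy - 2L), replace = TRUE))[seq_len(ploidy)]
    } else {
      sample(1:2, 1L)
    }
    add_record(loc$chrom, loc$pos0, refb, alts, gt_idx)
  }

  .write_vcf(records, genome, path, sample_name)
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), hap = integer(0), stringsAsFactors = FALSE)
  truth_df <- truth_df[order(truth_df$chrom, truth_df$pos, truth_df$hap), ,
                       drop = FALSE]
  rownames(truth_df) <- NULL
  list(path = path, truth = truth_df)
}

#' Brute-force off-target scan (test oracle)
#'
#' Tests every window on both strands by direct per-base set membership;
#' asymptotically slow but obviously correct. The minus strand is scanned by
#' reverse-complementing the sequence (the production scanner instead
#' reverse-complements the pattern), so the two routes are independent.
#'
#' @inheritParams scan_sequence
#' @return Hit data.frame with the same columns and ordering as
#'   [scan_sequence()].
#' @export
brute_force_scan <- function(target_label, seq, q, coord_map = NULL) {
  pam <- q$pam
  pattern <- if (pam$orientation == "three_prime")
    paste0(q$spacer, pam$pattern) else paste0(pam$pattern, q$spacer)
  pch <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  is_spacer <- if (pam$orientation == "three_prime")
    seq_along(pch) <= nchar(q$spacer) else seq_along(pch) > nchar(pam$pattern)
  m <- length(pch)
  useq <- gsub("[^ACGTN]", "N", toupper(seq))
  L <- nchar(useq)

  scan_frame <- function(s) {
    # returns rows (start0 in this frame, mismatches, display window)
    out <- list()
    if (L < m) return(out)
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    for (start in 0:(L - m)) {
      w <- ch[(start + 1L):(start + m)]
      mm <- 0L; pam_ok <- TRUE
      for (j in seq_len(m)) {
        hit <- w[j] %in% .IUPAC_SETS[[pch[j]]]
        if (is_spacer[j]) {
          if (!hit) mm <- mm + 1L
        } else if (!hit) {
          pam_ok <- FALSE; break
        }
      }
      if (pam_ok && mm <= q$max_mismatches) {
        disp <- w
        for (j in seq_len(m)) {
          if (is_spacer[j] && !(w[j] %in% .IUPAC_SETS[[pch[j]]]))
            disp[j] <- tolower(w[j])
        }
        out[[length(out) + 1L]] <- list(start = start, mm = mm,
                                        disp = paste(disp, collapse = ""))
      }
    }
    out
  }

  fwd <- scan_frame(useq)
  rc <- reverse_complement(useq)
  rev_ <- scan_frame(rc)

  pos <- c(vapply(fwd, `[[`, 0L, "start"),
           vapply(rev_, function(h) L - m - h$start, 0L))
  strand <- c(rep("+", length(fwd)), rep("-", length(rev_)))
  mm <- c(vapply(fwd, `[[`, 0L, "mm"), vapply(rev_, `[[`, 0L, "mm"))
  disp <- c(vapply(fwd, `[[`, "", "disp"), vapply(rev_, `[[`, "", "disp"))
  ord <- order(pos, strand)
  pos <- pos[ord]; strand <- strand[ord]; mm <- mm[ord]; disp <- disp[ord]

  ref_position <- if (!is.null(coord_map)) map_to_reference(coord_map, pos)
                  else rep(NA_integer_, length(pos))
  hits <- data.frame(query_id = rep(q$id, length(pos)),
                     target_label = rep(target_label, length(pos)),
                     position = as.integer(pos), strand = strand,
                     matched_seq = disp, mismatches = as.integer(mm),
                     ref_position = as.integer(ref_position),
                     stringsAsFactors = FALSE)
  class(hits) <- c("offtarget_hits", "data.frame")
  hits
}

# ---- end-to-end fixtures with planted allele-specific gains and losses ----

# Choose a PAM position (pattern frame, within the full pattern) whose IUPAC
# set is a proper subset of ACGT, so it can be broken/restored by a SNP.
.breakable_pam_index <- function(compiled) {
  idx <- which(!compiled$spacer_mask)
  idx <- idx[vapply(idx, function(j) {
    length(setdiff(c("A", "C", "G", "T"), .IUPAC_SETS[[compiled$chars[j]]])) > 0L
  }, logical(1))]
  if (!length(idx))
    stop("PAM has no constrained position; cannot plant a PAM-altering SNP")
  idx[sample.int(length(idx), 1L)]
}

# Guide-frame index j -> 0-based offset within the forward-strand genomic
# window, and the ref/alt genomic bases for a break (or its restoration).
.pam_snp <- function(compiled, guide_window, j, strand) {
  match_b <- substr(guide_window, j, j)
  broken_b <- .mismatch_base(compiled$chars[j])
  if (strand == "+") {
    list(offset = j - 1L, match = match_b, broken = broken_b)
  } else {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    list(offset = compiled$length - j, match = comp[[match_b]],
         broken = comp[[broken_b]])
  }
}

.subset_haps <- function(ploidy) {
  hs <- which(stats::runif(ploidy) < 0.5)
  if (!length(hs)) hs <- sample.int(ploidy, 1L)
  hs
}

.gt_for_haps <- function(ploidy, haps) {
  idx <- integer(ploidy)
  idx[haps] <- 1L
  idx
}

#' Simulate a complete planted-truth fixture
#'
#' Generates a random genome, plants exact off-target sites shared by all
#' sequences, variant-created gains (a reference window with a broken PAM
#' plus a phased SNP restoring it on chosen haplotypes; or a haplotype-only
#' insertion containing a full site), and variant-destroyed losses (an exact
#' reference site plus a phased PAM-breaking SNP), then overlays background
#' SNP/indel/MNP/multiallelic variants away from the planted windows, and
#' writes FASTA + VCF.
#'
#' @param seed Integer seed driving every draw.
#' @param dir Output directory for `ref.fa` and `sample.vcf`.
#' @param query A [guide_query()]; default: a random 20-nt spacer with the
#'   NRG PAM and 1 allowed mismatch.
#' @param n_chroms,chrom_length,gc_fraction Genome shape.
#' @param ploidy Haplotype count.
#' @param n_shared,n_gain_snp,n_loss_snp,n_gain_insertion Planted site counts.
#' @param background Named list of counts passed to [generate_phased_vcf()]
#'   (`n_snps`, `n_insertions`, `n_deletions`, `n_mnps`, `n_multiallelic`).
#' @return List: `ref_path`, `vcf_path`, `genome`, `query`, `ploidy`, and
#'   `truth` — data.frame of planted events (`type` in
#'   `shared`/`gain_snp`/`loss_snp`/`gain_insertion`, `chrom`, `ref_start`
#'   (0-based window start in the final reference; `NA` for insertion
#'   gains), `strand`, `haps` comma-joined 1-based haplotype indices the
#'   event applies to).
#' @export
simulate_fixture <- function(seed, dir = tempfile("fixture"),
                             query = NULL,
                             n_chroms = 2L, chrom_length = 3000L,
                             gc_fraction = 0.41, ploidy = 2L,
                             n_shared = 2L, n_gain_snp = 1L,
                             n_loss_snp = 1L, n_gain_insertion = 1L,
                             background = list(n_snps = 8L, n_insertions = 2L,
                                               n_deletions = 2L, n_mnps = 1L,
                                               n_multiallelic = 1L)) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- generate_genome(n_chroms, chrom_length, gc_fraction)
  if (is.null(query)) {
    spacer <- paste(sample(c("A", "C", "G", "T"), 20L, replace = TRUE),
                    collapse = "")
    query <- guide_query(spacer, pam_spec("NRG", "NRG", "three_prime"),
                         max_mismatches = 1L, id = "guide1")
  }
  compiled <- compile_pattern(query)
  m <- compiled$length
  pad <- 30L
  occupied <- list()
  extra <- list()
  truth <- list()

  reserve <- function(span) {
    for (try in 1:500) {
      chrom <- names(genome)[sample.int(length(genome), 1L)]
      L <- nchar(genome[[chrom]])
      pos0 <- sample.int(L - span - 2L * (pad + m), 1L) + pad + m
      if (!.overlaps_any(occupied, chrom, pos0 - pad, pos0 + span + pad)) {
        occupied[[length(occupied) + 1L]] <<-
          list(chrom = chrom, start = pos0 - pad, end = pos0 + span + pad)
        return(list(chrom = chrom, pos0 = pos0))
      }
    }
    stop("could not place planted site; enlarge the genome")
  }

  note <- function(type, chrom, ref_start, strand, haps) {
    truth[[length(truth) + 1L]] <<- data.frame(
      type = type, chrom = chrom, ref_start = ref_start, strand = strand,
      haps = paste(haps, collapse = ","), stringsAsFactors = FALSE)
  }

  for (i in seq_len(n_shared)) {
    loc <- reserve(m)
    strand <- sample(c("+", "-"), 1L)
    pl <- plant_site(genome, loc$chrom, loc$pos0, query, 0L, strand)
    genome <- pl$genome
    note("shared", loc$chrom, loc$pos0, strand, seq_len(ploidy))
  }

  for (i in seq_len(n_gain_snp)) {
    loc <- reserve(m)
    strand <- sample(c("+", "-"), 1L)
    r <- .realize_window(query, 0L, strand)
    j <- .breakable_pam_index(compiled)
    snp <- .pam_snp(compiled, r$guide_frame, j, strand)
    broken <- r$genomic
    substr(broken, snp$offset + 1L, snp$offset + 1L) <- snp$broken
    s <- genome[[loc$chrom]]
    genome[[loc$chrom]] <- paste0(substr(s, 1L, loc$pos0), broken,
                                  substr(s, loc$pos0 + m + 1L, nchar(s)))
    haps <- .subset_haps(ploidy)
    extra[[length(extra) + 1L]] <- data.frame(
      chrom = loc$chrom, pos1 = loc$pos0 + snp$offset + 1L,
      ref = snp$broken, alt = snp$match,
      gt = .gt_string(.gt_for_haps(ploidy, haps)), stringsAsFactors = FALSE)
    note("gain_snp", loc$chrom, loc$pos0, strand, haps)
  }

  for (i in seq_len(n_loss_snp)) {
    loc <- reserve(m)
    strand <- sample(c("+", "-"), 1L)
    r <- .realize_window(query, 0L, strand)
    s <- genome[[loc$chrom]]
    genome[[loc$chrom]] <- paste0(substr(s, 1L, loc$pos0), r$genomic,
                                  substr(s, loc$pos0 + m + 1L, nchar(s)))
    j <- .breakable_pam_index(compiled)
    snp <- .pam_snp(compiled, r$guide_frame, j, strand)
    haps <- .subset_haps(ploidy)
    extra[[length(extra) + 1L]] <- data.frame(
      chrom = loc$chrom, pos1 = loc$pos0 + snp$offset + 1L,
      ref = snp$match, alt = snp$broken,
      gt = .gt_string(.gt_for_haps(ploidy, haps)), stringsAsFactors = FALSE)
    note("loss_snp", loc$chrom, loc$pos0, strand, haps)
  }

  for (i in seq_len(n_gain_insertion)) {
    loc <- reserve(1L)
    strand <- sample(c("+", "-"), 1L)
    r <- .realize_window(query, 0L, strand)
    anchor <- substr(genome[[loc$chrom]], loc$pos0 + 1L, loc$pos0 + 1L)
    lpadseq <- paste(sample(c("A", "C", "G", "T"), 3L, replace = TRUE),
                     collapse = "")
    rpadseq <- paste(sample(c("A", "C", "G", "T"), 3L, replace = TRUE),
                     collapse = "")
    haps <- .subset_haps(ploidy)
    extra[[length(extra) + 1L]] <- data.frame(
      chrom = loc$chrom, pos1 = loc$pos0 + 1L, ref = anchor,
      alt = paste0(anchor, lpadseq, r$genomic, rpadseq),
      gt = .gt_string(.gt_for_haps(ploidy, haps)), stringsAsFactors = FALSE)
    note("gain_insertion", loc$chrom, NA_integer_, strand, haps)
  }

  bg <- generate_phased_vcf(
    genome, file.path(dir, "sample.vcf"),
    n_snps = background$n_snps %||% 8L,
    n_insertions = background$n_insertions %||% 2L,
    n_deletions = background$n_deletions %||% 2L,
    n_mnps = background$n_mnps %||% 1L,
    n_multiallelic = background$n_multiallelic %||% 1L,
    ploidy = ploidy, avoid = occupied, extra = extra)

  ref_path <- file.path(dir, "ref.fa")
  write_genome_fasta(genome, ref_path)
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(type = character(0), chrom = character(0),
               ref_start = integer(0), strand = character(0),
               haps = character(0), stringsAsFactors = FALSE)
  list(ref_path = ref_path, vcf_path = bg$path, genome = genome,
       query = query, ploidy = ploidy, truth = truth_df,
       background_truth = bg$truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
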
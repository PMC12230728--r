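# Parsing and canonicalization of phased single-sample VCF records into
# per-haplotype applicable variants.
#
# Coordinates are 0-based half-open everywhere inside the package; the VCF's
# 1-based POS is converted once, at the parser boundary. Missing or
# half-missing genotypes are dropped (with a counted warning), never filled
# with reference: silent reference-fill can fabricate haplotypes. Symbolic
# ALTs (<DEL>, breakends) are outside the small-variant scope and skipped.

.is_symbolic_alt <- function(alt) {
  grepl("^<", alt) | grepl("\\[|\\]", alt) | alt == "*"
}

#' One canonical variant
#'
#' @param chrom Sequence name.
#' @param pos 0-based reference coordinate of the first REF base.
#' @param ref,alt Uppercase DNA allele strings, each length >= 1.
#' @param line 1-based line number in the source VCF, for diagnostics.
#' @return A `variant_record` (named list).
#' @export
variant_record <- function(chrom, pos, ref, alt, line = NA_integer_) {
  ref <- toupper(ref); alt <- toupper(alt)
  if (nchar(ref) < 1L || nchar(alt) < 1L)
    stop("empty allele in variant at ", chrom, ":", pos)
  if (ref == alt)
    stop("ref and alt alleles identical at ", chrom, ":", pos)
  structure(list(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                 line = as.integer(line)),
            class = "variant_record")
}

#' @export
print.variant_record <- function(x, ...) {
  cat(sprintf("<variant> %s:%d %s>%s (vcf line %s)\n",
              x$chrom, x$pos, x$ref, x$alt,
              ifelse(is.na(x$line), "?", x$line)))
  invisible(x)
}

.parse_gt_string <- function(gt) {
  # Returns list(indices, phased, missing). A haploid call has no separator
  # and is trivially phased.
  gt <- strsplit(gt, ":", fixed = TRUE)[[1L]][1L]
  phased <- !grepl("/", gt, fixed = TRUE)
  fields <- strsplit(gt, "[|/]")[[1L]]
  missing <- any(fields == ".") || length(fields) == 0L
  idx <- suppressWarnings(as.integer(fields))
  list(indices = idx, phased = phased, missing = missing || anyNA(idx))
}

#' Parse a phased single-sample VCF
#'
#' Reads a VCF 4.x file (plain or bgzip) and extracts, for one sample, each
#' record together with its phased genotype. Records with missing or
#' half-missing genotypes are dropped with a counted warning. Ploidy is
#' inferred from the first usable genotype and enforced thereafter.
#'
#' @param path VCF file path.
#' @param sample Sample name; may be omitted when the file has exactly one.
#' @param assume_phased Accept `/`-separated genotypes as if phased.
#' @param pass_only Keep only records whose FILTER is `PASS` or `.`.
#' @return List with `records` (each: `chrom`, `pos` 0-based, `ref`, `alts`
#'   character vector, `gt` = list(indices, phased), `line`), `ploidy`,
#'   `sample`, and `warnings` (named skip counts).
#' @export
parse_vcf <- function(path, sample = NULL, assume_phased = FALSE,
                      pass_only = FALSE) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L)
    stop("VCF has no sample columns: ", path)
  samples <- colnames(gt)[-1L]
  if (is.null(sample)) {
    if (length(samples) > 1L)
      stop("multi-sample VCF; choose one of: ", paste(samples, collapse = ", "))
    sample <- samples[1L]
  } else if (!sample %in% samples) {
    stop("sample '", sample, "' not in VCF; available: ",
         paste(samples, collapse = ", "))
  }
  n_meta <- length(v@meta)

  warnings <- c(missing_genotype = 0L, not_pass = 0L)
  records <- list()
  ploidy <- NA_integer_
  n <- nrow(fix)
  for (i in seq_len(if (is.null(n)) 0L else n)) {
    line_no <- n_meta + 1L + i  # meta lines + #CHROM header + record index
    if (pass_only && !(fix[i, "FILTER"] %in% c("PASS", ".", NA))) {
      warnings["not_pass"] <- warnings["not_pass"] + 1L
      next
    }
    g <- .parse_gt_string(gt[i, sample])
    if (g$missing) {
      warnings["missing_genotype"] <- warnings["missing_genotype"] + 1L
      next
    }
    if (!g$phased && !assume_phased && length(g$indices) > 1L)
      stop("unphased genotype at line ", line_no,
           " (use assume_phased to override)")
    if (is.na(ploidy)) {
      ploidy <- length(g$indices)
    } else if (length(g$indices) != ploidy) {
      stop("ploidy changes from ", ploidy, " to ", length(g$indices),
           " at line ", line_no)
    }
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    if (any(g$indices > length(alts)))
      stop("genotype index exceeds ALT count at line ", line_no)
    records[[length(records) + 1L]] <- list(
      chrom = unname(fix[i, "CHROM"]),
      pos = as.integer(fix[i, "POS"]) - 1L,
      ref = unname(toupper(fix[i, "REF"])),
      alts = unname(toupper(alts)),
      gt = list(indices = g$indices, phased = g$phased),
      line = line_no
    )
  }
  if (warnings["missing_genotype"] > 0L)
    warning(warnings["missing_genotype"],
            " record(s) with missing genotype dropped")
  list(records = records, ploidy = ploidy, sample = sample,
       warnings = warnings)
}

# Decompose one REF/ALT pair into primitives: minimal SNVs plus at most one
# residual indel, by end-anchored comparison (shared suffix trimmed first,
# then shared prefix, each keeping at least one base per allele).
.decompose_pair <- function(pos, ref, alt, chrom, line) {
  lr <- nchar(ref); la <- nchar(alt)
  rch <- strsplit(ref, "", fixed = TRUE)[[1L]]
  ach <- strsplit(alt, "", fixed = TRUE)[[1L]]
  s <- 0L
  while (s < min(lr, la) - 1L && rch[lr - s] == ach[la - s]) s <- s + 1L
  p <- 0L
  while (p < min(lr - s, la - s) - 1L && rch[p + 1L] == ach[p + 1L]) p <- p + 1L
  core_r <- rch[(p + 1L):(lr - s)]
  core_a <- ach[(p + 1L):(la - s)]
  a <- length(core_r); b <- length(core_a)
  pos0 <- pos + p
  out <- list()
  if (a == b) {
    for (i in seq_len(a)) {
      if (core_r[i] != core_a[i])
        out[[length(out) + 1L]] <-
          variant_record(chrom, pos0 + i - 1L, core_r[i], core_a[i], line)
    }
  } else {
    k <- min(a, b)
    for (i in seq_len(k - 1L)) {
      if (core_r[i] != core_a[i])
        out[[length(out) + 1L]] <-
          variant_record(chrom, pos0 + i - 1L, core_r[i], core_a[i], line)
    }
    out[[length(out) + 1L]] <- variant_record(
      chrom, pos0 + k - 1L,
      paste(core_r[k:a], collapse = ""),
      paste(core_a[k:b], collapse = ""), line)
  }
  out
}

#' Decompose a record into allelic primitives
#'
#' MNPs and complex substitutions are split into the minimal set of SNVs
#' plus at most one residual indel per ALT allele; pure SNVs and simple
#' indels pass through unchanged. The operation is idempotent. Symbolic
#' ALTs (structural variants) are skipped with a warning.
#'
#' @param record A raw record as returned in `parse_vcf()$records`, or a
#'   [variant_record()].
#' @return List of `variant_record`s, each carrying an `alt_index` attribute
#'   (1-based index of the originating ALT allele).
#' @export
decompose_primitives <- function(record) {
  if (inherits(record, "variant_record")) {
    record <- list(chrom = record$chrom, pos = record$pos, ref = record$ref,
                   alts = record$alt, line = record$line)
  }
  out <- list()
  for (ai in seq_along(record$alts)) {
    alt <- record$alts[ai]
    if (.is_symbolic_alt(alt)) {
      warning("symbolic ALT '", alt, "' at line ", record$line,
              " skipped (structural variants unsupported)")
      next
    }
    if (!grepl("^[ACGTN]+$", alt) || !grepl("^[ACGTN]+$", record$ref)) {
      warning("non-ACGTN allele at line ", record$line, " skipped")
      next
    }
    if (alt == record$ref) next
    prims <- .decompose_pair(record$pos, record$ref, alt, record$chrom,
                             record$line)
    for (pr in prims) {
      attr(pr, "alt_index") <- ai
      out[[length(out) + 1L]] <- pr
    }
  }
  out
}

#' Assign a record's alternate alleles to haplotypes
#'
#' Each haplotype receives exactly the ALT its phased genotype index selects
#' (index 0: no variant). The per-haplotype representation makes the
#' re-merge of split multiallelic records unnecessary — an intentional
#' simplification relative to multiallelic round-tripping.
#'
#' @param record A raw record from `parse_vcf()$records`.
#' @param genotype Optional genotype list (`indices`, `phased`); defaults to
#'   `record$gt`.
#' @return A list with one element per haplotype, each a list of
#'   `variant_record`s (primitives) applying to that haplotype.
#' @export
split_multiallelic <- function(record, genotype = record$gt) {
  idx <- genotype$indices
  if (any(idx > length(record$alts)))
    stop("genotype index exceeds ALT count at line ", record$line)
  prims <- decompose_primitives(record)
  prim_alt <- vapply(prims, function(p) attr(p, "alt_index"), integer(1))
  lapply(idx, function(g) {
    if (g == 0L) list() else prims[prim_alt == g]
  })
}

#' Left-align and trim a variant to its canonical representation
#'
#' Produces the parsimonious, leftmost representation: the shared suffix is
#' trimmed (extending left through the reference whenever an allele would
#' empty), then the shared prefix is trimmed down to the single anchor base
#' an indel requires. SNVs are fixed points; the operation is idempotent.
#'
#' @param v A [variant_record()].
#' @param ref_seq The full sequence of `v$chrom` (character scalar), or a
#'   named character vector of chromosome sequences.
#' @return The normalized `variant_record`.
#' @export
normalize_left_align <- function(v, ref_seq) {
  if (!inherits(v, "variant_record")) stop("v must be a variant_record")
  if (!is.null(names(ref_seq))) {
    if (!v$chrom %in% names(ref_seq))
      stop("chromosome ", v$chrom, " not in reference")
    ref_seq <- ref_seq[[v$chrom]]
  }
  L <- nchar(ref_seq)
  if (v$pos < 0L || v$pos + nchar(v$ref) > L)
    stop("variant at ", v$chrom, ":", v$pos, " outside chromosome (length ", L, ")")
  obs <- substr(ref_seq, v$pos + 1L, v$pos + nchar(v$ref))
  if (obs != v$ref)
    stop("reference mismatch at ", v$chrom, ":", v$pos, ": VCF says '",
         v$ref, "', reference has '", obs, "' (line ", v$line, ")")
  rch <- strsplit(v$ref, "", fixed = TRUE)[[1L]]
  ach <- strsplit(v$alt, "", fixed = TRUE)[[1L]]
  pos <- v$pos
  repeat {
    nr <- length(rch); na_ <- length(ach)
    if (nr > 0L && na_ > 0L && rch[nr] == ach[na_]) {
      if ((nr == 1L || na_ == 1L) && pos == 0L) break  # cannot shift past start
      rch <- rch[-nr]; ach <- ach[-na_]
      if (length(rch) == 0L || length(ach) == 0L) {
        b <- substr(ref_seq, pos, pos)  # 1-based char at 0-based pos-1
        rch <- c(b, rch); ach <- c(b, ach); pos <- pos - 1L
      }
    } else break
  }
  while (length(rch) > 1L && length(ach) > 1L && rch[1L] == ach[1L]) {
    rch <- rch[-1L]; ach <- ach[-1L]; pos <- pos + 1L
  }
  variant_record(v$chrom, pos, paste(rch, collapse = ""),
                 paste(ach, collapse = ""), v$line)
}

#' Group per-haplotype variants into sorted, overlap-checked sets
#'
#' @param per_hap List (one element per haplotype) of lists of
#'   `variant_record`s, e.g. accumulated from [split_multiallelic()].
#' @param labels Haplotype labels; default `"allele1"`, `"allele2"`, ...
#' @param strict If `TRUE` (default) overlapping variants within a haplotype
#'   are an error naming both source lines; otherwise the first is kept and
#'   the rest skipped with a warning.
#' @return List of `haplotype_variant_set` objects: data.frames with columns
#'   `chrom`, `pos`, `ref`, `alt`, `line`, sorted by (chrom, pos), with a
#'   `label` attribute.
#' @export
build_haplotype_sets <- function(per_hap, labels = NULL, strict = TRUE) {
  P <- length(per_hap)
  if (is.null(labels)) labels <- paste0("allele", seq_len(P))
  out <- vector("list", P)
  for (h in seq_len(P)) {
    vs <- per_hap[[h]]
    df <- if (length(vs)) {
      data.frame(
        chrom = vapply(vs, `[[`, "", "chrom"),
        pos = vapply(vs, `[[`, 0L, "pos"),
        ref = vapply(vs, `[[`, "", "ref"),
        alt = vapply(vs, `[[`, "", "alt"),
        line = vapply(vs, `[[`, 0L, "line"),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                 alt = character(0), line = integer(0),
                 stringsAsFactors = FALSE)
    }
    df <- df[order(df$chrom, df$pos), , drop = FALSE]
    keep <- rep(TRUE, nrow(df))
    if (nrow(df) > 1L) {
      last_end <- df$pos[1L] + nchar(df$ref[1L])
      last_i <- 1L
      for (i in 2L:nrow(df)) {
        same <- df$chrom[i] == df$chrom[last_i]
        if (same && df$pos[i] < last_end) {
          if (strict)
            stop("overlapping variants on ", labels[h], " at ", df$chrom[i],
                 ":", df$pos[i], " (vcf lines ", df$line[last_i], " and ",
                 df$line[i], ")")
          warning("overlapping variant on ", labels[h], " at line ",
                  df$line[i], " skipped")
          keep[i] <- FALSE
        } else {
          last_end <- df$pos[i] + nchar(df$ref[i])
          last_i <- i
        }
      }
    }
    df <- df[keep, , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "label") <- labels[h]
    class(df) <- c("haplotype_variant_set", "data.frame")
    out[[h]] <- df
  }
  names(out) <- labels
  out
}

#' Full VCF-to-haplotype-variant-set pipeline
#'
#' Chains [parse_vcf()], [split_multiallelic()] (which decomposes to
#' primitives), [normalize_left_align()] and [build_haplotype_sets()].
#'
#' @inheritParams parse_vcf
#' @param ref Named character vector of chromosome sequences (see
#'   [read_reference_fasta()]).
#' @param strict Overlap handling, see [build_haplotype_sets()].
#' @return List with `sets` (per-haplotype variant sets), `ploidy`,
#'   `sample`, `warnings`.
#' @export
vcf_haplotype_sets <- function(path, ref, sample = NULL,
                               assume_phased = FALSE, pass_only = FALSE,
                               strict = TRUE) {
  parsed <- parse_vcf(path, sample = sample, assume_phased = assume_phased,
                      pass_only = pass_only)
  ploidy <- if (is.na(parsed$ploidy)) 2L else parsed$ploidy
  per_hap <- replicate(ploidy, list(), simplify = FALSE)
  n_symbolic <- 0L
  for (rec in parsed$records) {
    assigned <- withCallingHandlers(
      split_multiallelic(rec),
      warning = function(w) {
        if (grepl("symbolic ALT|non-ACGTN", conditionMessage(w)))
          n_symbolic <<- n_symbolic + 1L
        invokeRestart("muffleWarning")
      }
    )
    for (h in seq_len(ploidy)) {
      for (v in assigned[[h]]) {
        per_hap[[h]][[length(per_hap[[h]]) + 1L]] <-
          normalize_left_align(v, ref)
      }
    }
  }
  warnings <- c(parsed$warnings, symbolic_alt = n_symbolic)
  list(sets = build_haplotype_sets(per_hap, strict = strict),
       ploidy = ploidy, sample = parsed$sample, warnings = warnings)
}
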
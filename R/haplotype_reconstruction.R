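# Apply a haplotype's variant set to the reference to produce the allelic
# sequence, together with an invertible partial coordinate map.
#
# Collinearity convention: for every variant, the first min(len(ref),
# len(alt)) positions stay collinear (the map answers "where", not "what" —
# substituted SNV/MNP positions and the indel anchor base are mapped even
# though bases may differ); only the inserted or deleted tail has no image
# in the other frame.

#' Read a reference FASTA into a named character vector
#'
#' Sequences are uppercased on load (soft-masking is not preserved; search
#' semantics are case-insensitive). Names are the first whitespace-delimited
#' token of each header.
#'
#' @param path FASTA file (plain or gzip/bgzip).
#' @return Named character vector of chromosome sequences.
#' @export
read_reference_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Build one haplotype sequence from a reference chromosome
#'
#' Left-to-right splice of reference segments and ALT alleles. Each variant's
#' REF allele is re-checked against the reference at application time, which
#' guards against pairing a VCF with the wrong FASTA.
#'
#' @param ref_seq Reference chromosome sequence (character scalar).
#' @param variants A `haplotype_variant_set` data.frame (or any data.frame
#'   with `pos`, `ref`, `alt`, `line`), restricted to this chromosome,
#'   sorted and non-overlapping.
#' @param chrom Chromosome name recorded in the result.
#' @param label Haplotype label (default: the set's `label` attribute).
#' @return A `haplotype_sequence`: list with `label`, `chrom`, `seq`, and
#'   `map` (a `coord_map` with `blocks`, `ref_len`, `hap_len`).
#' @export
build_haplotype <- function(ref_seq, variants, chrom = "chr",
                            label = attr(variants, "label")) {
  if (is.null(label)) label <- "allele1"
  L <- nchar(ref_seq)
  n <- if (is.null(variants)) 0L else nrow(variants)
  pieces <- character(0)
  blocks <- list()
  cur_ref <- 0L
  cur_hap <- 0L
  if (n > 0L) {
    if (is.unsorted(variants$pos, strictly = FALSE))
      stop("variant set must be sorted by position")
    for (i in seq_len(n)) {
      pos <- variants$pos[i]
      ref <- variants$ref[i]
      alt <- variants$alt[i]
      lr <- nchar(ref); la <- nchar(alt)
      if (pos < cur_ref)
        stop("overlapping variants at ", chrom, ":", pos,
             " (vcf line ", variants$line[i], ")")
      if (pos + lr > L)
        stop("variant at ", chrom, ":", pos, " extends past chromosome end")
      obs <- substr(ref_seq, pos + 1L, pos + lr)
      if (obs != ref)
        stop("reference mismatch applying variant at ", chrom, ":", pos,
             ": expected '", ref, "', found '", obs, "' (vcf line ",
             variants$line[i], ")")
      gap <- pos - cur_ref
      if (gap > 0L) {
        pieces <- c(pieces, substr(ref_seq, cur_ref + 1L, pos))
        blocks[[length(blocks) + 1L]] <- c(cur_ref, cur_hap, gap)
        cur_ref <- cur_ref + gap
        cur_hap <- cur_hap + gap
      }
      pieces <- c(pieces, alt)
      collinear <- min(lr, la)
      blocks[[length(blocks) + 1L]] <- c(cur_ref, cur_hap, collinear)
      cur_ref <- cur_ref + lr
      cur_hap <- cur_hap + la
    }
  }
  if (cur_ref < L) {
    pieces <- c(pieces, substr(ref_seq, cur_ref + 1L, L))
    blocks[[length(blocks) + 1L]] <- c(cur_ref, cur_hap, L - cur_ref)
    cur_hap <- cur_hap + (L - cur_ref)
  }
  seq <- paste(pieces, collapse = "")

  expected_len <- L + sum(nchar(variants$alt)) - sum(nchar(variants$ref))
  if (n == 0L) expected_len <- L
  stopifnot(nchar(seq) == expected_len)

  b <- if (length(blocks)) {
    m <- do.call(rbind, blocks)
    df <- data.frame(ref_start = m[, 1], hap_start = m[, 2], length = m[, 3])
    # merge blocks contiguous in both frames
    keep <- c(TRUE, !(df$ref_start[-1] == df$ref_start[-nrow(df)] + df$length[-nrow(df)] &
                        df$hap_start[-1] == df$hap_start[-nrow(df)] + df$length[-nrow(df)]))
    grp <- cumsum(keep)
    merged <- do.call(rbind, lapply(split(df, grp), function(g) {
      data.frame(ref_start = g$ref_start[1], hap_start = g$hap_start[1],
                 length = sum(g$length))
    }))
    rownames(merged) <- NULL
    merged
  } else {
    data.frame(ref_start = integer(0), hap_start = integer(0),
               length = integer(0))
  }
  map <- structure(list(blocks = b, ref_len = L, hap_len = nchar(seq)),
                   class = "coord_map")
  structure(list(label = label, chrom = chrom, seq = seq, map = map),
            class = "haplotype_sequence")
}

#' @export
print.haplotype_sequence <- function(x, ...) {
  cat(sprintf("<haplotype_sequence> %s %s: %d bp (%d map blocks)\n",
              x$chrom, x$label, nchar(x$seq), nrow(x$map$blocks)))
  invisible(x)
}

.map_lookup <- function(starts, lengths, targets, pos) {
  # generic block lookup: map pos (frame of `starts`) to `targets` frame
  if (length(starts) == 0L) return(rep(NA_integer_, length(pos)))
  i <- findInterval(pos, starts)
  out <- rep(NA_integer_, length(pos))
  valid <- i >= 1L
  off <- pos[valid] - starts[i[valid]]
  inside <- off < lengths[i[valid]]
  idx <- which(valid)[inside]
  out[idx] <- as.integer(targets[i[valid]][inside] + off[inside])
  out
}

#' Map a haplotype coordinate to the reference
#'
#' @param m A `coord_map` from [build_haplotype()].
#' @param hap_pos 0-based haplotype position(s), each in `[0, hap_len)`.
#' @return Integer vector of reference coordinates; `NA` for positions
#'   inside inserted sequence (no reference image).
#' @export
map_to_reference <- function(m, hap_pos) {
  if (!inherits(m, "coord_map")) stop("m must be a coord_map")
  if (length(hap_pos) == 0L) return(integer(0))
  if (any(hap_pos < 0L | hap_pos >= m$hap_len))
    stop("haplotype position out of range [0, ", m$hap_len, ")")
  .map_lookup(m$blocks$hap_start, m$blocks$length, m$blocks$ref_start, hap_pos)
}

#' Map a reference coordinate to a haplotype
#'
#' Inverse of [map_to_reference()] on collinear positions.
#'
#' @param m A `coord_map`.
#' @param ref_pos 0-based reference position(s), each in `[0, ref_len)`.
#' @return Integer vector of haplotype coordinates; `NA` for deleted
#'   reference positions.
#' @export
map_from_reference <- function(m, ref_pos) {
  if (!inherits(m, "coord_map")) stop("m must be a coord_map")
  if (length(ref_pos) == 0L) return(integer(0))
  if (any(ref_pos < 0L | ref_pos >= m$ref_len))
    stop("reference position out of range [0, ", m$ref_len, ")")
  .map_lookup(m$blocks$ref_start, m$blocks$length, m$blocks$hap_start, ref_pos)
}

#' Build every haplotype sequence for every chromosome
#'
#' Chromosomes absent from a haplotype's variant set pass through verbatim
#' with identity maps.
#'
#' @param ref Named character vector of chromosome sequences.
#' @param sets List of `haplotype_variant_set`s from [build_haplotype_sets()]
#'   or [vcf_haplotype_sets()].
#' @return Nested list: `result[[label]][[chrom]]` is a
#'   `haplotype_sequence`.
#' @export
build_all_haplotypes <- function(ref, sets) {
  out <- list()
  for (h in seq_along(sets)) {
    set <- sets[[h]]
    label <- attr(set, "label")
    if (is.null(label)) label <- paste0("allele", h)
    per_chrom <- list()
    for (chrom in names(ref)) {
      vs <- set[set$chrom == chrom, , drop = FALSE]
      attr(vs, "label") <- label
      per_chrom[[chrom]] <- build_haplotype(ref[[chrom]], vs, chrom = chrom,
                                            label = label)
    }
    out[[label]] <- per_chrom
  }
  out
}

#' Write allelic FASTA files
#'
#' One record per chromosome per haplotype, headers `<chrom>_<label>`
#' (e.g. `chr1_allele1`), 60-column wrapping. The delimiter is the final
#' `_allele<k>` suffix, so chromosome names containing underscores parse
#' back unambiguously.
#'
#' @param haps Nested list from [build_all_haplotypes()], or a flat list of
#'   `haplotype_sequence`s.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_allelic_fasta <- function(haps, path) {
  flat <- list()
  for (el in haps) {
    if (inherits(el, "haplotype_sequence")) flat[[length(flat) + 1L]] <- el
    else for (hs in el) flat[[length(flat) + 1L]] <- hs
  }
  seqs <- vapply(flat, `[[`, "", "seq")
  names(seqs) <- vapply(flat, function(h) paste0(h$chrom, "_", h$label), "")
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Split an allelic FASTA header back into chromosome and allele label
#'
#' @param header Header string(s) of the form `<chrom>_allele<k>`.
#' @return data.frame with columns `chrom` and `label`.
#' @export
parse_allelic_header <- function(header) {
  m <- regmatches(header, regexec("^(.*)_(allele[0-9]+)$", header))
  bad <- vapply(m, length, 0L) != 3L
  if (any(bad)) stop("not an allelic header: ", header[bad][1L])
  data.frame(chrom = vapply(m, `[[`, "", 2L),
             label = vapply(m, `[[`, "", 3L),
             stringsAsFactors = FALSE)
}
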
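# Cas-OFFinder-style mismatch-tolerant scan for spacer+PAM patterns.
#
# Matching semantics: the PAM is matched degenerately (IUPAC) with zero
# tolerance; the mismatch budget applies to spacer positions only. A genome
# 'N' is an unknown base: it satisfies no concrete pattern base, only a
# pattern 'N'. Both strands are scanned; a minus-strand hit is reported at
# the forward-strand start of its window.

# IUPAC alphabet, genome alphabet, and the pattern-vs-genome match table.
.IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "N")
.GENOME_CODES <- c("A", "C", "G", "T", "N")

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T", "N")
)

.IUPAC_MATCH <- local({
  m <- matrix(FALSE, nrow = length(.IUPAC_CODES), ncol = length(.GENOME_CODES),
              dimnames = list(.IUPAC_CODES, .GENOME_CODES))
  for (p in .IUPAC_CODES) m[p, ] <- .GENOME_CODES %in% .IUPAC_SETS[[p]]
  m
})

.IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                       R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                       B = "V", D = "H", H = "D", V = "B", N = "N")

#' Degenerate base matching
#'
#' Tests whether a genome base is contained in the base set denoted by an
#' IUPAC pattern character. A genome `N` (unknown base) matches only a
#' pattern `N`; a concrete pattern base never matches genome `N`.
#'
#' @param pattern_base Single IUPAC character (one of ACGTRYSWKMBDHVN).
#' @param genome_base Single genome character (one of ACGTN).
#' @return Logical scalar (vectorized over equal-length inputs).
#' @examples
#' iupac_match("R", "G")  # TRUE: R = A or G
#' iupac_match("A", "N")  # FALSE: unknown base cannot be asserted to be A
#' @export
iupac_match <- function(pattern_base, genome_base) {
  pattern_base <- toupper(pattern_base)
  genome_base <- toupper(genome_base)
  if (!all(pattern_base %in% .IUPAC_CODES))
    stop("invalid IUPAC pattern character: ",
         paste(setdiff(pattern_base, .IUPAC_CODES), collapse = ", "))
  if (!all(genome_base %in% .GENOME_CODES))
    stop("invalid genome character: ",
         paste(setdiff(genome_base, .GENOME_CODES), collapse = ", "))
  .IUPAC_MATCH[cbind(pattern_base, genome_base)]
}

#' Reverse complement of an IUPAC string
#'
#' Degenerate complements follow the standard table (R<->Y, S<->S, W<->W,
#' K<->M, B<->V, D<->H, N<->N).
#'
#' @param s Character scalar over the IUPAC alphabet.
#' @return The reverse-complemented string.
#' @examples
#' reverse_complement("NRG")  # "CYN"
#' @export
reverse_complement <- function(s) {
  if (length(s) != 1L || is.na(s)) stop("s must be a single string")
  if (nchar(s) == 0L) return(s)
  ch <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
  bad <- setdiff(ch, names(.IUPAC_COMPLEMENT))
  if (length(bad)) stop("invalid IUPAC character: ", paste(bad, collapse = ", "))
  paste(rev(unname(.IUPAC_COMPLEMENT[ch])), collapse = "")
}

#' PAM specification
#'
#' @param name PAM name, e.g. `"NRG"` (SpCas9) or `"TTTN"` (AsCpf1).
#' @param pattern IUPAC pattern string.
#' @param orientation `"three_prime"` (PAM downstream of the spacer, Cas9
#'   convention) or `"five_prime"` (PAM upstream, Cpf1 convention).
#' @return A `pam_spec` object.
#' @export
pam_spec <- function(name, pattern, orientation = c("three_prime", "five_prime")) {
  orientation <- match.arg(orientation)
  pattern <- toupper(pattern)
  if (nchar(pattern) == 0L) stop("PAM pattern must be non-empty")
  ch <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  bad <- setdiff(ch, .IUPAC_CODES)
  if (length(bad))
    stop("PAM '", name, "': invalid IUPAC character: ", paste(bad, collapse = ", "))
  structure(list(name = name, pattern = pattern, orientation = orientation),
            class = "pam_spec")
}

#' @export
print.pam_spec <- function(x, ...) {
  cat(sprintf("<pam_spec> %s: %s (%s)\n", x$name, x$pattern, x$orientation))
  invisible(x)
}

#' Guide query: spacer + PAM + mismatch budget
#'
#' @param spacer Spacer sequence (ACGT, optionally N which never mismatches).
#' @param pam A [pam_spec()] object.
#' @param max_mismatches Non-negative spacer mismatch budget.
#' @param id Query label used in outputs.
#' @return A `guide_query` object.
#' @export
guide_query <- function(spacer, pam, max_mismatches = 0L, id = spacer) {
  spacer <- toupper(spacer)
  if (nchar(spacer) == 0L) stop("spacer must be non-empty")
  ch <- strsplit(spacer, "", fixed = TRUE)[[1L]]
  bad <- setdiff(ch, .IUPAC_CODES)
  if (length(bad))
    stop("spacer: invalid IUPAC character: ", paste(bad, collapse = ", "))
  if (!inherits(pam, "pam_spec")) stop("pam must be a pam_spec")
  max_mismatches <- as.integer(max_mismatches)
  if (is.na(max_mismatches) || max_mismatches < 0L)
    stop("max_mismatches must be a non-negative integer")
  structure(list(id = id, spacer = spacer, pam = pam,
                 max_mismatches = max_mismatches),
            class = "guide_query")
}

#' @export
print.guide_query <- function(x, ...) {
  cat(sprintf("<guide_query> %s: spacer %s + PAM %s (%s), k <= %d\n",
              x$id, x$spacer, x$pam$pattern, x$pam$name, x$max_mismatches))
  invisible(x)
}

#' Compile a guide query into strand-ready search patterns
#'
#' Builds the full forward-strand pattern (`spacer || pam` for a 3' PAM,
#' `pam || spacer` for a 5' PAM), labels each position spacer vs PAM so the
#' mismatch budget applies to the spacer only, and precomputes the
#' reverse-complement pattern for minus-strand scanning.
#'
#' @param q A [guide_query()].
#' @return A `compiled_query` list with elements `pattern`, `spacer_mask`,
#'   `rc_pattern`, `rc_spacer_mask`, `length`, and the originating query.
#' @export
compile_pattern <- function(q) {
  if (!inherits(q, "guide_query")) stop("q must be a guide_query")
  if (q$pam$orientation == "three_prime") {
    pattern <- paste0(q$spacer, q$pam$pattern)
    spacer_mask <- c(rep(TRUE, nchar(q$spacer)), rep(FALSE, nchar(q$pam$pattern)))
  } else {
    pattern <- paste0(q$pam$pattern, q$spacer)
    spacer_mask <- c(rep(FALSE, nchar(q$pam$pattern)), rep(TRUE, nchar(q$spacer)))
  }
  rc <- reverse_complement(pattern)
  structure(list(
    pattern = pattern,
    chars = strsplit(pattern, "", fixed = TRUE)[[1L]],
    spacer_mask = spacer_mask,
    rc_pattern = rc,
    rc_chars = strsplit(rc, "", fixed = TRUE)[[1L]],
    rc_spacer_mask = rev(spacer_mask),
    length = nchar(pattern),
    query = q
  ), class = "compiled_query")
}

#' Count spacer mismatches and test the PAM for one window
#'
#' @param compiled A [compile_pattern()] result.
#' @param window DNA string of the same length as the pattern.
#' @return List with `spacer_mismatches` (integer) and `pam_ok` (logical).
#' @export
count_mismatches <- function(compiled, window) {
  if (!inherits(compiled, "compiled_query")) stop("compiled must be a compiled_query")
  window <- toupper(window)
  if (nchar(window) != compiled$length)
    stop("window length ", nchar(window), " != pattern length ", compiled$length)
  wch <- strsplit(window, "", fixed = TRUE)[[1L]]
  ok <- iupac_match(compiled$chars, wch)
  list(spacer_mismatches = sum(!ok & compiled$spacer_mask),
       pam_ok = all(ok[!compiled$spacer_mask]))
}

# Vectorized single-strand scan kernel. `codes` is the sequence as integer
# indices into .GENOME_CODES (5 = N, including any non-ACGT input char).
# Returns start positions (0-based) and spacer mismatch counts.
.scan_kernel <- function(codes, pat_chars, spacer_mask, k) {
  L <- length(codes)
  m <- length(pat_chars)
  W <- L - m + 1L
  if (W <= 0L)
    return(list(pos = integer(0), mism = integer(0)))
  pat_idx <- match(pat_chars, .IUPAC_CODES)
  mism <- integer(W)
  pam_fail <- logical(W)
  for (j in seq_len(m)) {
    ok <- .IUPAC_MATCH[pat_idx[j] + (codes[j:(j + W - 1L)] - 1L) * nrow(.IUPAC_MATCH)]
    if (spacer_mask[j]) mism <- mism + !ok else pam_fail <- pam_fail | !ok
  }
  keep <- !pam_fail & mism <= k
  list(pos = which(keep) - 1L, mism = mism[keep])
}

.encode_genome <- function(seq) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  codes <- match(ch, .GENOME_CODES)
  codes[is.na(codes)] <- 5L  # anything non-ACGT behaves as unknown
  codes
}

# Lowercase the mismatching spacer positions of a matched window, read
# 5'->3' along the guide (Cas-OFFinder output convention).
.format_matched_seq <- function(window_fwd, compiled, strand) {
  if (strand == "+") {
    chars <- strsplit(toupper(window_fwd), "", fixed = TRUE)[[1L]]
    ok <- .IUPAC_MATCH[cbind(compiled$chars, ifelse(chars %in% .GENOME_CODES, chars, "N"))]
    low <- compiled$spacer_mask & !ok
  } else {
    disp <- reverse_complement(window_fwd)
    chars <- strsplit(disp, "", fixed = TRUE)[[1L]]
    ok <- .IUPAC_MATCH[cbind(compiled$chars, ifelse(chars %in% .GENOME_CODES, chars, "N"))]
    low <- compiled$spacer_mask & !ok
  }
  chars[low] <- tolower(chars[low])
  paste(chars, collapse = "")
}

#' Scan a sequence for off-target hits of a guide query
#'
#' Locates every window, on both strands, whose PAM matches degenerately and
#' whose spacer differs from the guide at no more than `q$max_mismatches`
#' positions. Hit positions are 0-based window starts on the forward strand
#' of the scanned sequence. When a coordinate map is supplied (a haplotype
#' scan), each hit also carries the mapped reference coordinate of its window
#' start, or `NA` where the start lies in inserted sequence.
#'
#' @param target_label Label for the scanned sequence (chromosome, or
#'   chromosome + allele).
#' @param seq DNA string (uppercased internally).
#' @param q A [guide_query()].
#' @param coord_map Optional [coord_map] from [build_haplotype()].
#' @return A data.frame of hits: `query_id`, `target_label`, `position`,
#'   `strand`, `matched_seq` (mismatched spacer bases lowercased, read along
#'   the guide), `mismatches`, `ref_position` (NA when unmappable), sorted by
#'   position then strand (`+` before `-`).
#' @export
scan_sequence <- function(target_label, seq, q, coord_map = NULL) {
  compiled <- compile_pattern(q)
  codes <- .encode_genome(seq)
  k <- q$max_mismatches

  fwd <- .scan_kernel(codes, compiled$chars, compiled$spacer_mask, k)
  rev_ <- .scan_kernel(codes, compiled$rc_chars, compiled$rc_spacer_mask, k)

  pos <- c(fwd$pos, rev_$pos)
  strand <- c(rep("+", length(fwd$pos)), rep("-", length(rev_$pos)))
  mism <- c(fwd$mism, rev_$mism)
  ord <- order(pos, strand)  # "+" < "-" in C locale ordering of these two chars
  pos <- pos[ord]; strand <- strand[ord]; mism <- mism[ord]

  m <- compiled$length
  matched <- character(length(pos))
  useq <- gsub("[^ACGTN]", "N", toupper(seq))
  for (i in seq_along(pos)) {
    window <- substr(useq, pos[i] + 1L, pos[i] + m)
    matched[i] <- .format_matched_seq(window, compiled, strand[i])
  }

  ref_position <- if (!is.null(coord_map)) {
    map_to_reference(coord_map, pos)
  } else {
    rep(NA_integer_, length(pos))
  }

  hits <- data.frame(
    query_id = rep(q$id, length(pos)),
    target_label = rep(target_label, length(pos)),
    position = as.integer(pos),
    strand = strand,
    matched_seq = matched,
    mismatches = as.integer(mism),
    ref_position = as.integer(ref_position),
    stringsAsFactors = FALSE
  )
  class(hits) <- c("offtarget_hits", "data.frame")
  hits
}

#' Write hits as TSV
#'
#' One hit per line; columns `query_id`, `target_label`, `position`,
#' `matched_seq`, `strand`, `mismatches`, `ref_position` (`.` when none);
#' `#`-prefixed header.
#'
#' @param hits Hit data.frame from [scan_sequence()].
#' @param path Output file path.
#' @param one_based Report 1-based coordinates instead of the default 0-based.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, path, one_based = FALSE) {
  off <- if (one_based) 1L else 0L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#coordinates=%s", if (one_based) "1-based" else "0-based"), con)
  writeLines("#query_id\ttarget_label\tposition\tmatched_seq\tstrand\tmismatches\tref_position", con)
  if (nrow(hits)) {
    refp <- ifelse(is.na(hits$ref_position), ".", as.character(hits$ref_position + off))
    writeLines(sprintf("%s\t%s\t%d\t%s\t%s\t%d\t%s",
                       hits$query_id, hits$target_label, hits$position + off,
                       hits$matched_seq, hits$strand, hits$mismatches, refp), con)
  }
  invisible(path)
}
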
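# Compare off-target hit sets across the reference and the haplotypes.
#
# Site identity across sequences uses the mapped reference coordinate of the
# window start (strand-aware): hits on different alleles whose starts map to
# the same reference coordinate are the same site even when their haplotype
# coordinates differ (e.g. downstream of a heterozygous deletion). Hits
# inside inserted sequence have no reference image and are never merged
# across alleles. Counts are per-allele totals, not deduplicated: a
# homozygous site counts once per allele.

.REF_SOURCE <- "reference"

#' Attach site identity keys to hits
#'
#' @param hits Hit data.frame carrying columns `query_id`, `chrom`,
#'   `position`, `strand`, `ref_position`, `source` (the string
#'   `"reference"` or an allele label).
#' @return The data.frame with an added `key` column. Reference hits are
#'   keyed by their own coordinate; allele hits by their mapped reference
#'   coordinate when collinear, else by their own frame (unmergeable).
#' @export
assign_site_keys <- function(hits) {
  need <- c("query_id", "chrom", "position", "strand", "ref_position", "source")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("hits lack columns: ", paste(miss, collapse = ", "))
  anchor <- ifelse(hits$source == .REF_SOURCE,
                   as.character(hits$position),
                   ifelse(is.na(hits$ref_position),
                          paste0("hap:", hits$source, ":", hits$position),
                          as.character(hits$ref_position)))
  hits$key <- paste(hits$query_id, hits$chrom, anchor, hits$strand, sep = "|")
  hits
}

#' Classify sites as shared, reference-only, or allele-specific
#'
#' @param ref_hits Reference hit data.frame (from [scan_sequence()]) with a
#'   `chrom` column.
#' @param allele_hits Named list (one element per allele label) of hit
#'   data.frames with `chrom` columns.
#' @return A `comparison_report`: list with `sites` (one row per site key:
#'   `query_id`, `chrom`, `strand`, `anchor`, `class` in
#'   `shared_all`/`reference_only`/`allele_subset`, `present_in`
#'   comma-joined, and one `pos_<source>` column per sequence giving the
#'   coordinate in that sequence's own frame, `NA` when absent) and
#'   `counts` (per-chromosome count table, see
#'   [summarize_per_chromosome()]).
#' @export
classify_sites <- function(ref_hits, allele_hits) {
  labels <- names(allele_hits)
  if (is.null(labels) || any(labels == ""))
    stop("allele_hits must be a named list of hit tables")
  # Sanity check: hit lists compared must come from the same query set. A
  # query may legitimately have zero hits on one sequence, so only flagrant
  # inconsistency (two non-empty lists with disjoint query sets) is an error.
  all_q <- lapply(c(list(ref_hits), allele_hits),
                  function(h) unique(h$query_id))
  nonempty <- all_q[vapply(all_q, length, 0L) > 0L]
  if (length(nonempty) > 1L) {
    for (i in 2L:length(nonempty)) {
      if (!length(intersect(nonempty[[1L]], nonempty[[i]])))
        stop("inconsistent query ids across hit lists")
    }
  }

  pile <- list()
  add <- function(h, source) {
    if (!nrow(h)) return()
    h$source <- source
    pile[[length(pile) + 1L]] <<- h[, c("query_id", "chrom", "position",
                                        "strand", "ref_position", "source")]
  }
  add(ref_hits, .REF_SOURCE)
  for (lab in labels) add(allele_hits[[lab]], lab)
  sources <- c(.REF_SOURCE, labels)

  if (!length(pile)) {
    sites <- data.frame(query_id = character(0), chrom = character(0),
                        strand = character(0), anchor = character(0),
                        class = character(0), present_in = character(0),
                        stringsAsFactors = FALSE)
    for (s in sources) sites[[paste0("pos_", s)]] <- integer(0)
  } else {
    all_hits <- assign_site_keys(do.call(rbind, pile))
    keys <- unique(all_hits$key)
    rows <- lapply(keys, function(k) {
      g <- all_hits[all_hits$key == k, , drop = FALSE]
      present <- unique(g$source)
      cls <- if (setequal(present, sources)) "shared_all"
             else if (identical(present, .REF_SOURCE)) "reference_only"
             else "allele_subset"
      anchor <- strsplit(k, "|", fixed = TRUE)[[1L]][3L]
      row <- data.frame(query_id = g$query_id[1L], chrom = g$chrom[1L],
                        strand = g$strand[1L], anchor = anchor, class = cls,
                        present_in = paste(sources[sources %in% present],
                                           collapse = ","),
                        stringsAsFactors = FALSE)
      for (s in sources) {
        p <- g$position[g$source == s]
        row[[paste0("pos_", s)]] <- if (length(p)) p[1L] else NA_integer_
      }
      row
    })
    sites <- do.call(rbind, rows)
    rownames(sites) <- NULL
  }

  counts <- summarize_per_chromosome(ref_hits, allele_hits)
  structure(list(sites = sites, counts = counts, sources = sources),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  tab <- table(factor(x$sites$class,
                      levels = c("shared_all", "reference_only", "allele_subset")))
  cat(sprintf("  sites: %d (%s)\n", nrow(x$sites),
              paste(names(tab), tab, sep = "=", collapse = ", ")))
  print(x$counts)
  invisible(x)
}

#' Per-chromosome hit count table
#'
#' Rows are (query, chromosome) pairs plus a totals row per query; columns
#' are the reference and each allele. Counts are per-allele totals on that
#' allele's sequence (the table arithmetic is independent of whether a
#' shifted site is "the same" site).
#'
#' @param ref_hits Reference hit data.frame with a `chrom` column.
#' @param allele_hits Named list of allele hit data.frames.
#' @return data.frame: `query_id`, `chrom`, `reference`, one column per
#'   allele label.
#' @export
summarize_per_chromosome <- function(ref_hits, allele_hits) {
  labels <- names(allele_hits)
  tabs <- c(list(reference = ref_hits), allele_hits)
  qids <- sort(unique(unlist(lapply(tabs, function(h) unique(h$query_id)))))
  chroms <- sort(unique(unlist(lapply(tabs, function(h) unique(h$chrom)))))
  grid <- expand.grid(chrom = chroms, query_id = qids,
                      stringsAsFactors = FALSE)[, c("query_id", "chrom")]
  for (nm in names(tabs)) {
    h <- tabs[[nm]]
    cnt <- integer(nrow(grid))
    if (nrow(h)) {
      t2 <- table(paste(h$query_id, h$chrom, sep = "\r"))
      cnt <- as.integer(t2[paste(grid$query_id, grid$chrom, sep = "\r")])
      cnt[is.na(cnt)] <- 0L
    }
    grid[[if (nm == "reference") "reference" else nm]] <- cnt
  }
  if (nrow(grid)) {
    totals <- do.call(rbind, lapply(split(grid, grid$query_id), function(g) {
      tot <- g[1L, , drop = FALSE]
      tot$chrom <- "total"
      for (col in setdiff(names(g), c("query_id", "chrom")))
        tot[[col]] <- sum(g[[col]])
      tot
    }))
    grid <- rbind(grid, totals)
    rownames(grid) <- NULL
  }
  grid
}

#' Write a comparison report as TSV files
#'
#' @param report A `comparison_report` from [classify_sites()].
#' @param counts_path,sites_path Output paths; `#`-prefixed header lines.
#' @param one_based Emit 1-based coordinates.
#' @return Invisibly, the two paths.
#' @export
write_report_tsv <- function(report, counts_path, sites_path,
                             one_based = FALSE) {
  off <- if (one_based) 1L else 0L
  con <- file(counts_path, "w")
  writeLines(paste0("#", paste(names(report$counts), collapse = "\t")), con)
  if (nrow(report$counts))
    utils::write.table(report$counts, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  close(con)

  s <- report$sites
  poscols <- grep("^pos_", names(s), value = TRUE)
  for (pc in poscols) s[[pc]] <- ifelse(is.na(s[[pc]]), ".",
                                        as.character(s[[pc]] + off))
  con <- file(sites_path, "w")
  writeLines(sprintf("#coordinates=%s", if (one_based) "1-based" else "0-based"), con)
  writeLines(paste0("#", paste(names(s), collapse = "\t")), con)
  if (nrow(s))
    utils::write.table(s, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  close(con)
  invisible(c(counts_path, sites_path))
}
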
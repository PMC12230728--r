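---
title: "Methods: haplotype-aware off-target search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: haplotype-aware off-target search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varoff)
```

## The problem and the model

A guide RNA directs a CRISPR nuclease to genomic windows that match its
spacer imperfectly, provided a protospacer-adjacent motif (PAM) sits next to
the window. Off-target surveys normally scan a reference assembly, but the
genome actually being edited differs from the reference by SNPs and small
indels, phased onto two (or more) haplotypes. Those variants can create,
destroy, or move potential off-target sites, and they can do so on one
haplotype only. `varoff` therefore treats the individual's genome as a set
of reconstructed allelic sequences and scans each of them, then reconciles
the hit sets through a coordinate map back to the reference.

A window $W$ of length $|S| + |P|$ is a hit for guide $(S, P, k)$ —
spacer $S$, IUPAC PAM pattern $P$, mismatch budget $k$ — iff

* every PAM position satisfies its IUPAC class (**zero tolerance**: the PAM
  is a binding requirement, not a similarity score), and
* the number of spacer positions where $W$ fails the spacer's class is
  at most $k$.

Both strands are scanned; a minus-strand hit is reported at the forward
window start, with its matched sequence read 5′→3′ along the guide and
mismatched spacer bases lowercased, a convention familiar from existing
off-target finders.

### Why the budget excludes the PAM

Published guide queries are conventionally written with a PAM placeholder
of Ns (e.g. a 22-mer = 19-nt spacer + `NNN`) next to a named PAM type; the
placeholder marks where the PAM sits, while the real constraint is the
named pattern. Treating PAM positions as freely mismatchable would collapse
that distinction, so the budget applies to the spacer alone. The choice is
explicit in the code (`count_mismatches` returns the PAM gate separately),
so a tolerant-PAM variant could be added without touching the kernel.

### Unknown bases

A genome `N` is an *unknown* base, not a wildcard: it satisfies only a
pattern `N`. Concretely, windows running through assembly gaps count those
positions as spacer mismatches and as PAM failures. This is conservative
and easy to reason about; the alternative (skipping N runs) silently
changes hit counts between assemblies with different masking.

## Variant canonicalization

The VCF path accepts phased, single-sample records (any ploidy ≥ 1) and
rejects unphased genotypes unless the caller explicitly asserts phasing —
an unphased het cannot be assigned to a haplotype, and guessing would
fabricate alleles. Missing and half-missing genotypes (`.`, `.|1`) are
dropped with a counted warning rather than treated as reference, for the
same reason. Symbolic ALTs (`<DEL>`, breakends) are outside the
small-variant scope and skipped with a counted warning.

Three transformations make records applicable:

1. **Primitive decomposition.** MNPs and complex substitutions are split by
   end-anchored comparison: the shared suffix is trimmed first, then the
   shared prefix (each keeping at least one base per allele), the
   equal-length overlap of what remains becomes SNVs and the length
   difference becomes one residual indel. The operation is idempotent and
   sequence-preserving; both properties are tested on random cases.
2. **Multiallelic split.** Each haplotype receives exactly the ALT its
   genotype index selects. Because the internal representation is
   per-haplotype from this point on, the round-trip step some pipelines
   perform — re-merging split records into multiallelic form — has nothing
   to act on; we document this as an intentional simplification, and the
   per-haplotype application is tested to preserve total allele content.
3. **Left alignment.** Indels are shifted to their leftmost
   sequence-equivalent representation and trimmed to parsimony (one anchor
   base). The implementation is the standard trim/extend loop; tests compare
   it against an oracle that *enumerates* every anchored representation and
   picks the leftmost, on repeat-rich sequences where shifting actually
   happens.

Within one haplotype, variants whose reference intervals overlap are an
error by default (`strict`), or first-kept-rest-skipped with warnings when
the caller opts in; silent resolution is never done.

## Haplotype reconstruction and the coordinate map

Each haplotype sequence is a left-to-right splice of reference segments and
ALT alleles. The coordinate map is a list of collinear blocks
`(ref_start, hap_start, length)` with two deliberate conventions:

* **Substituted positions stay collinear.** The map answers *where*, not
  *what*: an SNV/MNP position maps even though the base differs, because
  site identity across alleles is positional.
* **The indel anchor is collinear; only the inserted/deleted tail is not.**
  This maximizes the mappable fraction: a hit whose window starts on the
  anchor base still gets a reference coordinate.

`map_to_reference` / `map_from_reference` are exact inverses on collinear
positions and return `NA` inside insertions/deletions respectively. Length
conservation ($|H| = |R| + \sum (|alt| - |ref|)$) is asserted after every
build. Reference alleles are re-checked against the FASTA at application
time, which catches a mispaired VCF/FASTA immediately rather than
producing a silently wrong haplotype.

Soft-masked (lowercase) reference bases are uppercased on load: search
semantics are case-insensitive, and masking is not meaningful downstream.

## Allele comparison

Hits are keyed by `(query, chromosome, mapped reference window start,
strand)`. Hits inside inserted sequence have no reference image; they are
keyed in their own haplotype frame and *never merged across alleles* — two
haplotypes carrying the same insertion each report their own site. Classes
are `shared_all`, `reference_only` (present on no allele), and
`allele_subset` with the exact member set.

The per-chromosome count table is per-allele totals, deliberately **not**
deduplicated across alleles: a homozygous site counts once per allele.
This matches the arithmetic of reference-vs-allele count comparisons
regardless of whether a coordinate-shifted site is "the same" site, a
question the per-site classification answers separately.

## The synthetic fixture generator

`generate_genome` / `generate_phased_vcf` / `plant_site` /
`simulate_fixture` exist so that every stage is testable end to end with
planted ground truth and no external data. Design points:

* One seed, set once at each generator's entry, drives every draw; no
  wall-clock entropy. Identical specs give byte-identical FASTA/VCF/truth.
* Background variants (SNPs, insertions, deletions ≤ 20 bp, MNPs,
  multiallelic records, any ploidy) are spaced ≥ 30 bp apart and away from
  planted windows, so left-alignment shifts cannot make independent records
  collide and background variation cannot corrupt planted truth. Random
  DNA essentially never shifts an indel 30 bp.
* Gains and losses are planted through the PAM: a gain writes a window
  whose PAM is broken by one base with a phased SNP restoring it; a loss
  writes an exact site with a phased SNP breaking the PAM. Breaking the PAM
  (rather than adding spacer mismatches) makes the event decisive at any
  budget. Insertion gains embed a full site strictly inside inserted
  sequence, exercising the unmappable-key path.
* Default shape — 2 × 3 kb chromosomes, diploid, ~14 background variants,
  a random 20-nt spacer with the NRG PAM and $k = 1$ — is an edit-density
  and guide-length regime typical of resequenced individuals, scaled to
  desk size.

What the generator does **not** emulate: real mutation-rate heterogeneity,
linked variants and phasing errors, repeat-driven variant clustering,
assembly gaps, and structural variants. Passing the planted-truth suite
shows the pipeline's bookkeeping is exact under clean conditions; it does
not certify behavior on variant clusters that overlap within a haplotype
(which the strict mode rejects rather than resolves).

## Numerical and interface choices

* Coordinates are 0-based half-open everywhere internally; the VCF's
  1-based positions are converted once at the parser boundary. Output TSVs
  default to 0-based (search-tool convention) with `--one-based` for the
  VCF-minded; the dialect is stamped in the TSV header.
* Hit lists are canonically ordered (position, then `+` before `-`), so
  the scan kernel may process chromosomes and alleles in any order and
  outputs remain byte-reproducible.
* FILTER is ignored by default (`pass_only` restricts to PASS/`.`): a
  single-sample phased VCF has usually been filtered upstream, and
  default-permissive matches common consensus-building practice.
* bgzip-compressed inputs are accepted but no tabix index is required:
  indexing is an I/O optimization for random access, not semantics, and
  the pipeline reads sequentially.
* The shipped PAM catalog (YAML) carries NRG/NGG/NAG/NNGRRT (3′) and
  TTTN/TTTV (5′); catalogs are user-editable and validated on load
  (unique names, IUPAC alphabet, known orientation).

## Test problem sizes

The property suites run at sizes chosen to exercise the invariants while
keeping the whole suite fast on one core: 200 random scan instances of
1–10 kb (spacers 15–25 nt, budgets 0–4) against the brute-force oracle;
50 reconstruction fixtures (diploid and tetraploid, indels ≤ 20 bp) for
map round-trips; 500 repeat-rich indels for left-alignment; 50 end-to-end
planted gain/loss fixtures; plus the null-VCF and monotonicity checks.
`scripts/acceptance.R` recomputes all of these from scratch with a
caller-supplied seed.

## Known limitations

* Structural variants are out of scope; only SNVs and small indels are
  applied.
* No DNA/RNA bulge search and no activity scoring (CFD/MIT): hits are
  classified by mismatch count only.
* Site identity across alleles is positional (mapped window start,
  strand-aware). A variant that *moves* a site by destroying it at one
  locus and creating it nearby is reported as one loss and one gain, not a
  relocation.
* Overlapping variants within a haplotype are rejected, not resolved; a
  graph representation would be needed to apply nested edits faithfully.
* The scan kernel is pure R (vectorized per pattern position). It is
  comfortable at the multi-megabase scale; whole-mammalian-genome scans
  would want a compiled kernel behind the same contract.
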
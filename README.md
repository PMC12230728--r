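# varoff — variant-aware CRISPR off-target site search on phased haplotypes

CRISPR off-target prediction is usually run against a reference genome, but
off-target landscapes differ between individuals: a SNP can create a
functional PAM (gaining a cut site on one haplotype), destroy a protospacer,
or an insertion can carry a whole new site that the reference never shows.
`varoff` finds guide-RNA potential off-target sites not only on a reference
genome but on **each phased haplotype** of an individual, and reports which
sites are shared, gained, or lost per allele — for anyone designing guides
for personalized therapeutic editing or for specific crop cultivars.

## What it computes

Given a reference FASTA, a phased single-sample VCF, and one or more guides
(spacer + named PAM), the pipeline:

1. **Canonicalizes variants** — phased genotypes are read per haplotype;
   multiallelic records are split by genotype index; MNPs/complex
   substitutions are decomposed into allelic primitives (SNVs plus at most
   one indel); every variant is left-aligned to its parsimonious, leftmost
   representation.
2. **Reconstructs allelic sequences** — each haplotype's variant set is
   spliced into the reference, producing per-chromosome haplotype sequences
   plus an invertible coordinate map (collinear blocks; positions inside
   insertions/deletions have no image in the other frame).
3. **Scans for off-target sites** — every window on both strands whose PAM
   matches degenerately (IUPAC, zero tolerance) and whose spacer differs at
   ≤ *k* positions is a hit:

   a window `W` matches guide `(S, PAM)` iff every PAM position satisfies
   its IUPAC class and `Σᵢ [Wᵢ ≠ Sᵢ] ≤ k` over spacer positions.

   Hit positions are window starts in the scanned sequence's own frame,
   with the mapped reference coordinate as an extra column.
4. **Compares alleles** — hits are keyed by strand-aware mapped reference
   coordinate (hits inside insertions keep their own frame and are never
   merged) and classified `shared_all` / `reference_only` /
   `allele_subset`, with per-chromosome count tables (reference vs each
   allele).

PAM types (`NRG`, `NGG`, `TTTN`, ...) live in a user-editable YAML catalog;
any ploidy ≥ 1 is supported; structural variants are out of scope.

## Worked example

The package ships a seeded fixture generator that plants known
allele-specific sites, so you can watch the classification work:

```r
library(varoff)
fx <- simulate_fixture(42, dir = tempfile())   # 2 chroms, diploid VCF
fx$truth
#>             type chrom ref_start strand haps
#> 1         shared  chr2      1869      +  1,2
#> 2         shared  chr1       259      -  1,2
#> 3       gain_snp  chr1      2719      +    2
#> 4       loss_snp  chr1       573      -    1
#> 5 gain_insertion  chr2        NA      +    2

res <- run_pipeline(fx$ref_path, fx$vcf_path,
                    guides = data.frame(id = "guide1", spacer = fx$query$spacer),
                    pam = "NRG", max_mismatches = 1)
res$counts
#>   query_id chrom reference allele1 allele2
#> 1   guide1  chr1         2       1       3
#> 2   guide1  chr2         1       1       2
#> 3   guide1 total         3       2       5
res$report$sites[, c("chrom", "strand", "anchor", "class", "present_in")]
#>   chrom strand          anchor         class                present_in
#> 1  chr1      -             259    shared_all reference,allele1,allele2
#> 2  chr1      -             573 allele_subset         reference,allele2
#> 3  chr2      +            1869    shared_all reference,allele1,allele2
#> 4  chr1      +            2719 allele_subset                   allele2
#> 5  chr2      + hap:allele2:844 allele_subset                   allele2
```

Reading the output: the two planted shared sites are `shared_all`; the
PAM-destroying SNP on allele 1 leaves its site in `reference,allele2`
(lost on allele 1); the PAM-restoring SNP on allele 2 creates a site seen
only there; and the site planted inside an allele-2 insertion has no
reference coordinate (`hap:allele2:844` — its own frame) and can never be
merged across alleles. The count table is plain per-allele totals, so
allele 2 carries 5 sites vs 3 on the reference.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/varoff.R run --ref ref.fa --vcf sample.vcf \
    --guide GTGAAATCTAAGTGTAGAG --pam NRG --max-mismatches 3 --out-dir out/
```

Subcommands `reconstruct`, `search`, `compare`, `simulate` expose the
stages individually; staged runs compose to the monolithic `run`
byte-for-byte.

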
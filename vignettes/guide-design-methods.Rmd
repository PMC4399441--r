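---
title: "Guide selection and oligo design: methods and design choices"
author: "guidecraft"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guide selection and oligo design: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guidecraft)
```

## The problem

Cas9, directed by a guide RNA, cuts genomic DNA 3 bp upstream of an NGG
protospacer-adjacent motif (PAM) wherever the guide's 20 nt spacer matches.
In *S. cerevisiae* a double-strand break is lethal unless repaired, and the
dominant repair pathway is homologous recombination; supplying a repair
fragment that lacks the cut site therefore selects for the desired edit
without any marker. Designing such an experiment means choosing a spacer
that (a) will be transcribed intact, (b) cuts nowhere else in that strain's
genome, and (c) is likely to be active — and then deriving a handful of
oligonucleotides whose sequence is fully determined by the genome, the
spacer, and the plasmid backbone. Every step is deterministic string
manipulation, which is exactly what this package implements.

## Candidate enumeration

Candidates are every 20 nt window followed by NGG, on both strands of the
ORF, with the full 23 nt window required to lie inside the ORF. Requiring
the PAM inside the ORF keeps the cut intragenic and avoids candidates whose
PAM depends on flanking sequence. The N slot of the PAM must be a called
base (A/C/G/T); spacers containing an ambiguous base are retained in the
output but flagged `ambiguous_base`, since neither off-target scanning nor
scoring is meaningful for them. Coordinates are 0-based half-open
internally (arithmetic-safe) and 1-based inclusive in every user-facing
file.

## Filters

**Poly-T.** RNA polymerase III terminates on T runs, truncating the gRNA.
A spacer is discarded when it contains ≥ 6 *consecutive* T. The total
T count is deliberately irrelevant: a spacer with nine scattered T and a
maximum run of four is a perfectly usable guide (one of the validated
published targets has exactly that composition), so a total-count reading
would be wrong. The run is evaluated on the 20 nt spacer as written; the
PAM is not part of the transcribed guide and is excluded.

**Off-targets.** A genomic site counts as an off-target when it has ≥ 17 of
20 nucleotides identical to the spacer (Hamming distance ≤ 3, no
indels/bulges) and is followed on the same strand by NGG or NAG — NAG
because Cas9 retains substantial activity on NAG PAMs. Any off-target
discards the candidate; no position-weighted scoring (CFD/MIT-style) is
attempted, matching the conservative discard-on-any-hit rule. The
candidate's own site is excluded positionally (interval + strand equality),
not by counting, so a perfect duplicate elsewhere in the genome correctly
discards the candidate.

The scanner is an exact pigeonhole seed-and-extend: the spacer is split
into four disjoint 5-mer seeds; a site within 3 mismatches must match at
least one seed exactly; seed hits are collected from a per-chromosome 5-mer
position index and verified by exact Hamming recount and PAM gate. Genome
N is never indexed, counts as a mismatch during verification, and never
completes a PAM. An independent position-by-position exhaustive scan
(separate vectorized code path that shares no matching logic with the
production scanner) serves as the test oracle; the suite asserts
hit-for-hit identity on planted genomes up to 120 kb. Each discard records
a reason, and the reasons are derived from independent flags under a fixed
priority (`ambiguous_base` > `polyT` > `offtarget`), which makes the
filters idempotent and order-independent.

## Scoring and ranking

Three components are computed per surviving candidate and normalized per
locus:

* **AT fraction** — (#A + #T)/20, exact. Higher AT content correlates with
  higher cleavage activity in yeast.
* **RNA pairing** — the spacer is transcribed to RNA and folded; the score
  counts spacer nucleotides inside brackets of the dot-bracket structure.
  Fewer predicted intramolecular pairs means the seed region is more
  available for target pairing. The default backend is ViennaRNA's
  `RNAfold` maximum expected accuracy structure at 30 °C (yeast growth
  temperature) with lonely pairs disallowed. When `RNAfold` is not on the
  PATH, a bundled base-pair-maximization folder (Nussinov dynamic program;
  Watson–Crick + GU wobble pairs, minimum hairpin loop of 3) substitutes
  with a warning. By default only the 20 nt spacer is folded; folding
  spacer + scaffold is available via `score_config(fold_molecule =
  "spacer_plus_scaffold")`. Published per-target RNA scores are not
  asserted anywhere in the package: they depend on the folding engine
  version and on whether the scaffold was included, neither of which is
  recoverable, so the suite checks structural properties instead (pairing
  parity and bounds, balanced brackets, and equivalence of the fallback
  folder with exhaustive structure enumeration on short sequences).
* **Restriction presence** — 1 if any enzyme of the configured list cuts
  within the 20 nt spacer (either strand), else 0. A site inside the
  spacer lets a plasmid assembly be verified by digest. Only the spacer is
  scanned because only the spacer is carried into the plasmid. The default
  list ships the seven enzymes needed for the published target set (PvuI,
  EcoRV, DraI, EcoRI, KpnI, BamHI, PvuII) and is extensible via a TSV of
  IUPAC sites.

Normalization is per locus min–max: the highest-AT candidate gets AT = 1,
the least-paired candidate gets RNA = 1. When a component is degenerate
(all candidates equal) it is set to 0.5 for everyone — neutral, so ordering
falls to the other components; any constant would do, 0.5 keeps the rank
sums centered. The rank sum adds enabled components with equal weight, and
any component can be disabled. Ties are broken deterministically: higher
raw AT fraction, then smaller genomic start, then "+" strand first. Scores
are comparable within one locus only.

## Construction oligos

All designs are pure functions of genome, spacer and a `BackboneConfig`.
The plasmid backbones themselves are distributed through a strain
repository and are not bundled; the 50 nt flanks, the shared 50 nt
homology of the single-primer-linearized double-gRNA backbone and the
2µm-annealing sequence are therefore configuration (JSON), with synthetic
deterministic values generated for testing. The annealing sequence
defaults to 20 nt, a typical primer 3' footprint.

* *Single-gRNA insert*: `flank5 (50) + spacer (20) + flank3 (50)`, emitted
  as two complementary 120 nt strands to be annealed.
* *Deletion repair*: last 60 nt upstream + first 60 nt downstream of the
  ORF — recombination across the break removes the ORF scarlessly, and the
  suite verifies that the spacer+PAM no longer occurs afterwards (no
  re-cutting).
* *Mutation repair*: the 120-mer centered on the edited base (60 nt each
  side; no offset convention is published, and centering maximizes the
  shorter homology arm). If the guide's spacer+PAM still matches the
  edited sequence a warning — not an error — is raised: an edit outside
  the PAM can still be installed, re-cutting merely lowers efficiency, and
  resequencing after plasmid removal is the appropriate control.
* *Double-gRNA primers*: `homology (50) + spacer (20) + anneal`, one per
  target.
* *Integration tails*: the first fragment's 5' tail and last fragment's 3'
  tail are the 60 nt genomic junctions (identical to the deletion-repair
  arms); each internal junction tail copies the terminal 60 nt of the
  neighboring cassette, giving every junction a 60 bp overlap.

## Assembly and digest simulation

Because the double-gRNA backbone is linearized with a single primer, both
its ends carry the same homology, and the 2µm template carries the
annealing site at both ends in opposite orientations — so each tailed
primer can prime either end. The simulation enumerates the four equally
likely end assignments, builds each circular assembly, and counts spacer
copies by exact substring scan on both strands with circular wrap-around.
With distinct spacers exactly the two mixed assignments carry one copy of
each spacer: the expected 50% correct-assembly fraction. Synthetic stuffer
sequences stand in for the 2µm core and backbone interior (both are
deterministic defaults, overridable); copy counting is still an honest
substring count on the assembled circle.

`digest_check` locates recognition sites on both strands with wrap-around
and returns sorted fragment lengths per enzyme. Cut coordinates are taken
at the site start: fragment lengths depend only on inter-site distances,
which are invariant to the fixed within-site cut offset of any single
enzyme. Fragment lengths always sum to the plasmid length; an enzyme
without a site reports "uncut" (empty vector) rather than one full-length
fragment.

## Synthetic genomes

`make_genome` emulates exactly what the algorithms consume: chromosomes of
i.i.d. uniform A/C/G/T background, gene features as plain spans, planted
spacer+PAM sequences inside genes, and decoy 20-mers at exact Hamming
distances with chosen PAMs elsewhere. The background is screened with the
exhaustive scanner — not the production scanner, so fixture correctness is
independent of the code under test — for accidental ≤ 3-mismatch NGG/NAG
neighbors of any planted spacer, and re-sampled on collision (bounded
retries). Everything is deterministic per seed, down to the FASTA bytes.

What the generator does *not* emulate: codon structure, GC skew, repeats,
transposons and paralogous gene families. Passing tests demonstrate that
the algorithms implement their rules exactly; they do not demonstrate that
a repeat-rich real genome leaves many candidates per locus (in real yeast
ORFs the off-target filter discards far more candidates than in i.i.d.
background). Test genomes are kept at 4–10 kb for unit tests and ~120 kb
for the scanner-equivalence check, sizes at which the exhaustive oracle
remains fast.

## Numerical and degenerate-input choices

* Empty candidate sets (ORF < 23 nt, or no GG dinucleotide) are valid
  empty results, not errors; a gene whose candidates are all discarded is
  reported as "no valid target" with a discard tally and a non-zero exit
  from the CLI.
* The Nussinov fallback breaks ties toward the j-unpaired branch during
  traceback; any optimal structure has the same pair count, which is all
  the score uses.
* Locus flanks truncate at chromosome ends; repair design errors name the
  deficit (deletion repair needs ≥ 60 nt on each side).
* All sorting uses radix order on fixed keys; no step draws random numbers
  outside the seeded generators, so identical inputs give byte-identical
  outputs — verified by the suite.
* The ranked-target table, oligo FASTA/TSV and JSON report are rewritten
  only with an explicit overwrite flag.

## Limitations

* Hamming-only off-target matching: DNA or RNA bulges are not modeled.
* No on-target efficacy model (Doench/Azimuth-style) and no melting
  temperature or secondary-structure checks on the construction oligos.
* GFF3 features of type `gene` (or `CDS` grouped by parent) are used as
  genomic spans; introns are not spliced out, which matches the ORF-level
  design convention for yeast but would misplace cut sites in intron-rich
  genomes.
* Cross-locus score comparison is meaningless by construction; the ranked
  list answers "which target within this gene", nothing more.
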
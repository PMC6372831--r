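---
title: "Methods: mining and interpreting endogenous circoviral elements"
author: "circomine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mining and interpreting endogenous circoviral elements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Endogenous circoviral elements (CVe) are fragments of ancient
circovirus genomes fixed in vertebrate germlines. Two properties make
them informative: orthologous copies in different species must predate
those species' divergence, giving minimum-age calibrations for the
virus family; and their decay state (frameshifts, premature stops)
records how long they have been evolving neutrally. This package
implements the desk workflow that turns genome assemblies plus a viral
reference library into a dated, named CVe catalog, together with a
synthetic-data generator that makes every stage falsifiable offline.

# Screening model

The screen is a two-step translated similarity search. Step one
searches each assembly contig in all six reading frames with protein
probes (Rep and Cap). Exact `word_size`-mer seeds (default 4 residues)
are located in the translated frame, seed neighbourhoods are merged
into windows, and each window is mined greedily for non-overlapping
gapped local alignments (Smith–Waterman, BLOSUM62, affine gaps 11/1,
implemented in C++). Because the per-frame search within a window is
exhaustive, a hit split by a frameshift reappears as a weaker,
genomically overlapping alignment in another frame; these frame
shadows are filtered best-first (overlap allowance 30 nt or 25% of the
shorter hit). With `word_size = 1` the search degenerates to
exhaustive Smith–Waterman over the whole frame — the equivalence of
the seeded and exhaustive paths is a tested invariant, and
`Biostrings::pairwiseAlignment` serves as an independent oracle for
the scores.

Significance uses the Karlin–Altschul bit-score transform
`S' = (lambda * S - ln K) / ln 2` with the ungapped BLOSUM62 constants
`lambda = 0.318`, `K = 0.13`, and `E = m * n * 2^-S'` with m the probe
length and n the translated frame length. Applying ungapped constants
to gapped scores is a documented approximation: thresholds act on the
equivalent raw score, and no downstream decision depends on E-value
precision. The default cut-off is `E <= 1e-5`. Codons containing N
translate to `X`, which scores 0 against everything; the source
procedure's own cut-offs are unpublished, so all values are explicit
parameters recorded in run manifests.

Hits on one contig and strand merge into a locus when their gap is at
most `max_gap = 1000` nt — chosen so a ~2 kb circovirus genome split
by one deletion still merges. Loci carry up to 1 kb of flanking
sequence each side, reported in locus orientation; a flank is
*incomplete* when truncated by the contig edge or interrupted by an
N run of 50+ nt, the two failure modes that block orthology
confirmation in real assemblies.

One consequence of strand-aware merging deserves note: a head-to-tail
tandem array of a full ambisense genome screens as interleaved
plus-strand (rep) and minus-strand (cap) loci whose same-gene gaps
exceed `max_gap`. The array is reunited at the element level (below),
not by loosening hit merging.

# Classification and reference mapping

Each locus is translated in six frames and aligned locally against
every reference polypeptide. The best bit score assigns the closest
reference and gene; ties break by reference coverage, then
lexicographic ID. A locus above threshold against both gene classes is
`rep+cap`; below threshold everywhere it is `unknown` (a result, not
an error). The locus footprint is mapped through the reference CDS
table into genome coordinates (protein interval × 3, oriented by CDS
strand), and coverage is the unioned fraction of the reference genome
— computed from reference coordinates rather than a whole-genome
alignment, which keeps it exact and testable.

# Ancestral ORF reconstruction

Disruption counting uses a local protein-to-DNA dynamic program in
which each reference residue is consumed by a pseudo-codon of 1–5 nt.
Non-triplet codons change the running frame offset and are charged a
frameshift penalty of 15, above the codon gap-open cost (12, extension
2 per codon) so the alignment prefers clean codon gaps over spurious
slips; protein-side gaps consume whole codons only. Each non-triplet
move on the optimal path is one frameshift event; a stop codon aligned
to a non-terminal reference position is a premature stop. Ties resolve
toward the in-frame move, so equal-score paths carry the fewest
frameshifts. A locus is *intact* when it has no frameshifts, no
premature stops, and covers at least 95% of the reference CDS
(configurable).

Counting is exact for disruptions separated by roughly 12 codons or
more. Closer compensating slips (e.g. +1 then −1 within a few codons)
are absorbed by the score-optimal path as a run of substitutions —
two frameshift penalties cost more than briefly mistranslating — and
a +1/+2 pair collapsing to a codon gap is likewise cheaper than two
slips. This is the intended behaviour of a parsimony criterion, and it
bounds what the disruption-recovery tests may assert; the independent
plain-R rewrite of the recursion is the oracle for the C++ kernel.

# Orthology and event counting

Orthologous insertions share flanking host sequence. Corresponding
flanks (upstream↔upstream, downstream↔downstream in locus
orientation) are aligned globally with free end gaps; a pair is
*confirmed* when at least one flank pair with both sides complete
aligns at ≥ 80% identity over ≥ 100 nt. Pairs without usable flank
evidence are *potential* when the locus sequences themselves align at
≥ 70% identity over a substantial overlap (at least 100 nt and half
the shorter locus — the aligned-length floor exists because free-end
alignments of unrelated sequences find short perfect overlaps by
chance) and the loci share a reference footprint. Everything else is
*rejected*, including all same-species pairs, which are handled by
within-species merging instead. The thresholds are not from the source
study (which does not state any); they were chosen to separate
neutral-decay orthologs from random flanks under the simulator's rate
range and are configurable.

Within one species, loci on a contig within 10 kb whose reference
footprints do not overlap are conservatively merged into one element —
the fragmented remains of a single acquisition — and same-footprint
loci in close series (gaps ≤ 2.5 kb, about one genome length) are
treated as a tandem array, which counts as a single element. Element
candidates on different contigs without flank evidence stay separate
but flagged ambiguous. `element_groups()` then joins elements across
species through confirmed edges; this is the unit of event counting.
Potential edges never promote a group to confirmed.

Event counting is deliberately conservative: one event per group,
modified by explicit conventions — `collapse` pools all groups of a
clade into one event in the minimum bound, `exclude-tentative` drops
flagged groups from the minimum, and `split` lets a group contribute a
recorded number of alternative subunits to the maximum. On the
packaged 26-group catalog, collapsing the seven ray-finned-fish groups
and excluding the tentative hagfish group yields the published window
of 19–26 incorporation events.

# Dating

Ages are read from a user-supplied ultrametric timetree (branch
lengths in My; ultrametricity enforced to 1e-6 of the root age), never
estimated from sequence. The minimum age of a group is the age of the
MRCA of its species; a single-species group has minimum age 0. The
maximum age is the age of the shallowest node separating a group
member from a *screened* species lacking the element — absence is only
informative for screened assemblies. Published node-age uncertainty
(e.g. a 72–90 My divergence window) is carried as per-node ranges in a
sidecar table and propagated as intervals. Estimates based on
potential orthologs are labelled as such and never pooled with
confirmed ones.

# Naming and summaries

Identifiers follow `CVe-<Group>.<N>-<SpeciesTag>[-<dup>]`: the group
name (usually the host clade), an insertion number shared by
orthologs across species, a six-letter genus+species tag, and a copy
number for within-species duplicates. The period between group and
number follows the source's methods text; its results text uses a
hyphen there, so the parser accepts both dialects. Numbering is
deterministic (group discovery order, then genomic coordinates), and
uniqueness is enforced.

The packaged group catalog transcribes the published screen at group
resolution: 26 groups, 179 locus records, 53 species rows. The source
tables disagree internally — the text says 52 distinct species where
the table's totals row says 53, and the per-species carnivore copy
sum (108) exceeds the text's 101 — so the fixture follows the
group-level table whose per-group counts sum to the printed totals,
and records the carnivore group at the text's 101. On these numbers
the largest single-origin duplicated group (Carnivora) holds
101/179 = 56.4% of the catalog, which the source prints as 57%; the
package reports the exact ratio alongside its integer rounding rather
than reproducing the source's rounding. Species identities below
group resolution are not fully recoverable from the tables, so
expanded locus records carry count-preserving placeholder species
labels — sufficient for every summary statistic, and clearly
documented as synthetic.

# Duplication expansions and repeat association

Duplicate loci of an element are compared by p-distance over shared
ungapped columns (pairs sharing under half the alignment are flagged
unreliable), clustered with neighbor joining (`ape::nj`; exact
recovery of additive matrices is a tested invariant), and the
midpoint-rooted tree — a display heuristic matching the field's
convention — is scanned for maximal monophyletic single-lineage
clades of at least 3 leaves (the smallest clade size the motivating
figures treat as an expansion). Association between expansion
membership and repeat-adjacent flanks (any repeat annotation within
500 nt of the locus) is tested with a two-sided exact test computed by
full hypergeometric enumeration, with the Haldane 0.5 correction for
odds ratios with empty cells. The repeat track is a user-supplied BED
(in practice, retroelement annotations); querying an external repeat
database is deliberately out of scope so the stage stays offline.

# The synthetic-data generator

The simulator emulates exactly the phenomena the pipeline must
detect: insertion on a chosen branch of a dated host tree (all
descendant species inherit the insertion at homologous coordinates
with shared ancestral flanks), independent per-lineage neutral decay
in proportion to time since insertion, head-to-tail tandem arrays,
LINE-style co-mobilisation (extra copies of cassette+element at random
positions within a lineage), and assembly fragmentation with N runs.
Background host sequence is i.i.d. nucleotide at a specified GC and
deliberately repeat-free apart from injected cassettes; contig lengths
are drawn once and shared across species so planted positions are
homologous by construction.

Decay follows a per-site Poisson substitution process with uniform
choice among the other three bases — so the expected p-distance to the
source after time t at rate r is the Jukes–Cantor value
`0.75 (1 − exp(−4 r t / 3))`, a tested calibration — plus geometric
indels (mean 2 nt, insertions and deletions equally likely) and
optional targeted stop gains. Rates are user parameters, not
estimates: no substitution-rate calibration exists for CVe decay. The
study conditions used throughout the tests are substitutions at
0.001–0.004 per site per My, indels at 0–1e-4 per site per My, and
insertion times at the branch midpoint unless a scenario pins them;
these were fixed when the generator was written. What passing tests
show is therefore recovery under neutral decay in repeat-free
background; real assemblies add repeat-induced false joins,
composition bias and alignment ambiguity that the generator does not
model.

# Numerical and procedural choices

* Coordinates are 0-based half-open internally and in BED; GFF3
  export converts to 1-based inclusive.
* Seeds reproduce outputs bit-exactly; every stochastic helper takes
  an explicit seed.
* The exact 2×2 test enumerates the hypergeometric support directly
  on log-binomial coefficients; two-sided p sums tables no more
  probable than the observed one (relative tolerance 1e-7, matching
  the standard implementation, which serves as an oracle in tests).
* Unalignable loci (frameshift DP score below 40) report no
  disruption counts rather than zeros.
* Problem sizes in the test-suite property checks — e.g. 20 oracle
  assemblies of ~30 kb, 200 recovery seeds, 500 disruption loci, 40
  orthology simulations, 200 dating scenarios, exact-test enumeration
  to n = 40 — are the package's chosen verification scale: large
  enough for the properties to be sharp, small enough to run
  routinely.

# Known limitations

* The screen is protein-homology based; insertions diverged beyond
  ~50% amino-acid identity from every probe are invisible, as in the
  source procedure.
* E-values are approximate (ungapped constants); raw-score thresholds
  are the operative criterion.
* Orthology uses flank identity, not genome-wide synteny; potential
  orthologs approximate the source's phylogenetic-consistency check
  with locus identity plus shared footprint (maximum-likelihood
  phylogenetics is out of scope).
* Maximum-age bounds inherit detection failures: a carrier species
  whose locus is missed becomes a false screened negative.
* The published-screen fixture operates at group resolution; claims
  about individual real genomes are outside what the fixture can
  support.
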
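---
title: "Substitution patterns from PAML ancestral reconstructions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substitution patterns from PAML ancestral reconstructions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pamlsubs)
```

## The problem

When `baseml` or `codeml` (from the PAML suite) is run with ancestral
reconstruction enabled, it writes an auxiliary `rst` file containing the
maximum-likelihood reconstruction of every internal-node sequence and, for
every branch of the tree, the list of inferred unique substitutions. That
file holds a complete, branch-resolved substitution history of the
alignment, but its format is not easy to read, especially for alignments
with thousands of inferred changes. `pamlsubs` turns it into quantitative
summaries: every substitution is classified by type
(transition/transversion), codon position, and phenotypic effect
(synonymous/nonsynonymous), and the classified events are aggregated into
per-site profiles, sliding-window series, cumulative curves, a substitution
matrix and per-branch tree annotations.

The intended inputs are reconstructions of **protein-coding alignments
free of gaps and ambiguous bases**; rapidly evolving RNA virus genomes are
the motivating use case. A gap or ambiguity code anywhere in a sequence is
treated as a hard parse error, because a single indel shifts the reading
frame of every downstream codon and silently corrupts all synonymy calls.

## Event classification

Each change record on a branch `parent..child` at nucleotide site $s$ is
classified as follows:

* **Codon coordinates.** Codon index $\lceil s/3 \rceil$ and codon position
  $((s-1) \bmod 3) + 1$; coordinates are 1-based nucleotide positions, as
  printed in the rst file.
* **Mutation class.** A↔G and C↔T are transitions (Ts); the four other
  unordered base pairs are transversions (Tv).
* **Effect.** The codon context is taken from the **parent** node's
  reconstructed sequence, with only the changed base substituted. The event
  is synonymous if the parent codon and the altered codon translate to the
  same amino acid under the standard genetic code, nonsynonymous otherwise.
* **Category.** The class/effect cross gives the four-way split used
  throughout: synonymous transitions (**As**), synonymous transversions
  (**Bs**), nonsynonymous transitions (**Aa**), nonsynonymous transversions
  (**Ba**).

The parent-context rule is a deliberate design choice. PAML reports changes
as parent → child, so the pre-substitution reading frame is the parent's.
When two sites of one codon change on the same branch, each event is
evaluated against the parent codon with only that site altered — the two
events are treated independently. This is a documented simplification: the
true joint path through the codon is not reconstructed (doing so would
require an ordering of the within-branch changes that the rst file does not
provide). For codeml documents, the codons and amino acids printed in the
rst file are cross-checked against this derivation; disagreement raises a
warning rather than an error, since PAML's printed states can reflect
reconstruction ambiguity.

A stop codon implied on either side of a change aborts classification:
valid coding alignments cannot contain stops, so one appearing mid-pipeline
signals corrupt input, not an analyzable event.

## Summaries

**Per-site profile.** Exact integer tallies of As/Bs/Aa/Ba at every
nucleotide site, plus the per-site Ts/Tv totals and a 12 × 3 table of each
ordered base change by codon position.

**Sliding windows.** Windows start at 1, 1 + step, … while a full window
fits; trailing partial windows are dropped so per-window means stay
comparable. Each window value is the arithmetic mean of the per-site counts.
Defaults are `window = 90` nt (30 codons) and `step = 9` nt (3 codons) —
fine enough to resolve sub-gene features at the scale of a typical
picornavirus coding region while smoothing single-site noise; both are
plain arguments and changing them never touches the profile, so windows can
be re-tuned cheaply. Windows are **not** forced to codon boundaries: any
nucleotide window is allowed, and the codon-aware view is provided by the
position-stratified plots instead.

**dN/dS as used here — an important caveat.** `dS = As + Bs` and
`dN = Aa + Ba` are *raw substitution counts*, and the exported dN/dS is the
ratio of their window means. No normalization by the number of synonymous
and nonsynonymous *sites* (NG86/GY94-style) is applied. The ratio is
therefore a descriptive scan statistic for locating regions of elevated
amino-acid change, not a calibrated selection estimator: because roughly
three times more random changes are nonsynonymous than synonymous, a
neutrally evolving region will sit above 1 on this scale. Windows with
`dS = 0` yield an undefined marker (`NA`), rendered as a gap in plots and
an empty cell in tables — never infinity.

**Cumulative curves.** Running totals of As, Bs, Aa, Ba and the grand total
Kt, evaluated every `step` sites; the final alignment position is always
included, so the last Kt equals the total event count. Flat stretches of
the synonymous curve flag candidate regions of mutational saturation.

**Substitution matrix.** A 4 × 4 count matrix over (ancestral base, derived
base) with zero diagonal, exported under two normalizations: *conditional*
(each row divided by its total — a Markov matrix of conditional
substitution probabilities given the ancestral base) and *joint* (each cell
divided by the total event count — relative frequencies of the twelve
change types). Both describe the same tally and both are written to the
reports, clearly labeled; rows with no observed substitutions are left
all-zero and flagged rather than filled with NaN.

## Tree annotation

Per-branch summaries use a compact grammar: `18_1@Ts1_3@Ts2_2@Tv1` means
sequence (child node) 18 carries one transition at codon position 1, three
transitions at position 2 and two transversions at position 1. Segment
order is fixed as Ts before Tv with positions ascending, and zero-count
cells are omitted; `format_annotation()` and `parse_annotation()` are exact
inverses on this grammar. Amino-acid changes are written
`<fromAA><codon index><toAA>` (e.g. `L45P`) and the underlying nucleotide
changes `<from base><site><to base>` in lower case (e.g. `a263t`); both are
package conventions, stated here because the annotation grammar itself does
not fix them.

Two Newick trees are exported per run: one whose branches carry the
inferred amino-acid changes, one with the corresponding nonsynonymous
nucleotide changes. Annotations ride in FigTree-compatible
`[&aa="..."]` / `[&nt="..."]` bracket comments attached to the child node
of each branch. The writer and comment-aware reader are implemented in the
package (a small recursive serializer; plain topology parsing is delegated
to `ape::read.tree`), because mainstream R tree packages write plain Newick
only. `highlight_branches()` answers queries such as "all branches with a
transition at codon position 2", replacing interactive tree inspection with
a scriptable operation.

## Outputs

`analyze_rst()` writes eleven PDF plots (per-site Ts and Tv by codon
position; change types by position; synonymous and nonsynonymous per-site
profiles; windowed category means; windowed dS and dN; windowed dN/dS;
cumulative synonymous, nonsynonymous and total curves), two CSV reports and
the two annotated trees, plus a JSON run manifest. Report 1 stacks every
plotted series in long format (`sheet`, `position`, `series`, `value`);
report 2 holds the per-branch annotation table and the full classified
event list, distinguished by a `sheet` column. Two files rather than a
multi-sheet workbook keeps the output portable and diff-able; every number
in both reports is recomputable from the event list alone, and regenerating
the reports from the exported events reproduces them byte-identically. An
XLSX writer was considered and not included: the reports are views, and CSV
serializes them without extra dependencies.

## The simulator and what the tests do (and do not) show

`simulate_substitutions()` generates ground-truth histories: a root
sequence drawn uniformly over the 61 sense codons, a Poisson number of
substitutions per branch placed at distinct sites, and target bases drawn
with transition:transversion odds $\kappa : 1$ (each transversion
alternative carries half the transversion weight). Proposals creating a
stop codon — in the parent-frame codon or in the accumulating child
sequence — are rejected and redrawn. `write_rst()` serializes a history in
either rst dialect, so the parser, classifier and every summary can be
checked for *exact* agreement with the logged events, and the matrix-based
transition fraction can be checked against the closed-form expectation
$\kappa/(\kappa+1)$ within binomial error.

The simulator emulates format and count structure, not biology: no
rate heterogeneity across sites, no realistic codon model (GY94/ω), no
branch-length-driven expected counts, and posteriors are decorative draws
in [0.90, 1.00]. Passing tests therefore demonstrate that the pipeline
reproduces a known substitution history exactly and that its statistics
have the stated algebraic properties — they do not validate PAML's
reconstruction itself, nor the biological interpretation of any real data
set. One edge of the scheme is worth noting: as $\kappa \to \infty$ a small
fraction of events are still transversions, because at sites where the
transition target is a stop codon the rejection rule forces a transversion;
the tests assert exactly this limiting behavior.

Problem sizes used in the test-suite and acceptance runs — trees of 6–30
tips, alignments of 20–400 codons, up to ~10,000 events for the
kappa-recovery check, and 300 seeded random fixtures for the
parser-totality property — were chosen to make stochastic checks
well-powered (3-standard-error bands on ≥ 10,000 draws) while keeping a
full run comfortably fast on a laptop.

## Numerical and degenerate-input choices

* Posterior probabilities are parsed and carried but not used analytically;
  the default posterior threshold is 0 (count every inferred change), and
  filtering is opt-in.
* Zero-event runs are valid: all eleven plots render with zero series and
  empty axes rather than erroring, and reports contain the headers with no
  event rows.
* Unrecognized lines in an rst file are skipped with a warning carrying the
  line number (PAML versions differ in their chatter); lines that look like
  change records but fail to parse are hard errors with the line number.
* Row normalization guards: zero-count matrix rows divide by 1 and are
  flagged, keeping the probability matrix free of NaN.
* The parser rebuilds the tree from the branch records themselves (the
  numbered Newick supplies tip names); rst node numbering — tips `1..n`,
  ancestors `n+1..2n-1` — is preserved as the `phylo` numbering.

## Known limitations

* Only the standard genetic code is supported; the code table is a single
  named vector and could be swapped, but alternative tables are untested.
* Multi-site codon changes on one branch are classified independently
  against the parent codon (see above).
* dN/dS is count-based, not site-normalized (see above).
* Amino-acid-alphabet `baseml` runs, PAML main output files (`mlb`/`mlc`),
  likelihoods and model parameters are out of scope: the package consumes
  the reconstruction, it does not re-estimate anything.
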
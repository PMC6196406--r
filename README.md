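# pamlsubs

Substitution-pattern analysis from PAML ancestral reconstructions.

When `baseml` or `codeml` (PAML) is run with ancestral reconstruction
enabled it writes an auxiliary `rst` file: the reconstructed sequence of
every internal tree node plus, branch by branch, the list of inferred
unique substitutions. That file contains a complete branch-resolved
substitution history of a protein-coding alignment, but it is hard to read
at any scale. `pamlsubs` is for molecular evolutionists — in particular
people studying rapidly evolving RNA viruses — who want that history turned
into quantitative, plottable summaries.

Every inferred change is classified three ways:

* **mutation class** — transition (Ts: A↔G, C↔T) or transversion
  (Tv: A↔C, A↔T, G↔C, G↔T);
* **codon position** — 1, 2 or 3, from its 1-based nucleotide site;
* **effect** — synonymous or nonsynonymous, judged against the *parent*
  node's codon with only the changed base substituted.

crossing class and effect gives the four categories used throughout:
synonymous transitions **As**, synonymous transversions **Bs**,
nonsynonymous transitions **Aa**, nonsynonymous transversions **Ba**. From
the classified events the package computes per-site profiles,
sliding-window means with `dS = As + Bs`, `dN = Aa + Ba` and their ratio
(**note:** raw counts, not site-normalized rates — see the vignette),
cumulative curves including the running total Kt, and a 4×4 Markov matrix
of conditional substitution probabilities. It exports eleven PDF plots,
two CSV reports, and two FigTree-compatible annotated Newick trees (one
with amino-acid changes such as `L45P`, one with the underlying
nonsynonymous nucleotide changes such as `a263t`). Per-branch summaries use
the compact grammar `18_1@Ts1_3@Ts2_2@Tv1`: sequence 18 has one transition
at codon position 1, three at position 2 and two transversions at
position 1.

A seeded codon-evolution simulator (`simulate_substitutions()` +
`write_rst()`) generates synthetic rst files with exact event logs, so the
whole pipeline is testable without running PAML.

## Worked example

```r
library(pamlsubs)

# a known substitution history on a 10-tip tree, 300 codons
log <- simulate_substitutions(tips = 10, length_codons = 300, kappa = 4,
                              events_per_branch = 20, seed = 42)
rst <- tempfile(fileext = ".rst")
write_rst(log, "codeml", file = rst)

res <- analyze_rst(rst, "example_out", window = 90, step = 9)
res$document
#> PAML rst document (codeml)
#>   10 taxa, alignment length 900 nt
#>   18 branches, 355 inferred substitutions

table(res$events$category)
#>  Aa  As  Ba  Bs
#> 179  97  61  18

conditional_probabilities(res$matrix)
#> substitution_matrix: 355 events
#>     to
#> from  A  C  G  T
#>    A  0  8 83 10
#>    C 11  0 11 58
#>    G 69 12  0  8
#>    T  6 66 13  0
#> conditional probabilities:
#>     to
#> from      A      C      G      T
#>    A 0.0000 0.0792 0.8218 0.0990
#>    C 0.1375 0.0000 0.1375 0.7250
#>    G 0.7753 0.1348 0.0000 0.0899
#>    T 0.0706 0.7765 0.1529 0.0000

head(res$windows[, c("start", "dS", "dN", "dNdS")], 4)
#>   start        dS        dN     dNdS
#> 1     1 0.1666667 0.2555556 1.533333
#> 2    10 0.1666667 0.2888889 1.733333
#> 3    19 0.2000000 0.3333333 1.666667
#> 4    28 0.2000000 0.3444444 1.722222

format_annotation(res$annotations[[1]])
#> [1] "1_6@Ts1_7@Ts2_2@Ts3_1@Tv1_1@Tv2_3@Tv3"
```

Reading the numbers: the simulation was run at transition/transversion
ratio kappa = 4, and the conditional matrix recovers it — each row puts
roughly 0.72–0.82 of its mass on the transition cell (expected 4/5). Of
the 355 substitutions, 115 are synonymous (As + Bs) and 240 nonsynonymous
(Aa + Ba); with count-based dN and dS and a uniform-codon simulator, a
windowed dN/dS around 1.5–1.7 reflects the larger nonsynonymous target
size, not positive selection (see the vignette's caveat). The annotation
string says branch-child sequence 1 carries 6 transitions at codon
position 1, 7 at position 2, 2 at position 3, and single transversions at
positions 1 and 2 plus three at position 3.

`example_out/` now holds the eleven plots (`01_*.pdf` … `11_*.pdf`),
`report_plot_data.csv`, `report_tree_data.csv`, `tree_aa_changes.nwk`,
`tree_nt_changes.nwk` and `run_manifest.json`.

A thin command-line wrapper with `analyze`, `simulate` and `annotate`
subcommands is installed at `inst/cli/pamlsubs`:

```sh
Rscript inst/cli/pamlsubs simulate --out-dir sim --tips 10 --seed 1
Rscript inst/cli/pamlsubs analyze --input sim/simulated.rst --out-dir results
```

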
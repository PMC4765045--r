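---
title: "Exon-aware paralog-to-contig assignment: model, solver and benchmark design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exon-aware paralog-to-contig assignment: model, solver and benchmark design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exontig)
```

## The assignment model

`exontig` is built around one optimisation problem. A gene family of `N`
paralogous query proteins is decomposed into translated coding exons
(TCEs), numbered consistently so that homologous exons across paralogs
share a TCE group number `k = 1..m` (missing exons simply stay unmatched).
A fragmented target assembly contributes `n` contigs, each assumed to
harbour at most one gene of interest — very long contigs with several loci
must be split by the user beforehand. Similarity search yields bitscores
`theta[i,j,k]` of TCE `k` of paralog `j` on contig `i`; entries that are
absent after filtering count as zero and mean "no acceptable match".

The solver chooses binary variables `C[i,j]` (paralog `j` lives on contig
`i`) and `E[i,j,k]` (TCE `k` of paralog `j` is realised on contig `i`)
maximising `sum mu[i] * theta[i,j,k] * E[i,j,k]` subject to: each `(j,k)`
used at most once; at most one paralog per contig; no assignment without a
positive hit; `C` and `E` linked in both directions; an assigned contig
takes *all* TCE groups present on it; and no `E` for TCE types absent from
the contig. `mu[i]`, the number of TCE groups with a positive score on
contig `i`, weights the objective so that solutions keeping many exons on
one contig are preferred over scatterings with slightly larger raw score
sums.

Two modelling assumptions matter in practice. First, each exon type is
assumed to occur at most once per contig; when a hit table violates this
(tandem repeats, split hits), `build_instance()` keeps the best bitscore
per `(i,j,k)` cell. Second, the family's exon-intron structure must be
largely conserved; families with permuted exon orders fall outside the
model.

### The all-take constraint and its two readings

The constraint that an assigned contig takes all its TCE groups can be
read two ways, and they differ exactly when paralog `j` lacks hits for
some group that *another* paralog does hit on contig `i`:

* **per-contig (default)**: `mu[i] * C[i,j] <= sum_{k in K[i,j]} E[i,j,k]`
  with `K[i,j] = {k : theta[i,j,k] > 0}`. Since `|K[i,j]| <= mu[i]`, this
  forbids assigning `j` to `i` unless `j` covers *every* group found on
  the contig. This is the strict reading and is what `solve_pcap()`
  enforces by default; it is also slightly protective in the benchmark,
  because a paralog that misses a group another paralog found is usually
  the wrong owner.
* **per-paralog (`relaxed_eq7 = TRUE`)**: `mu[i]` is replaced by
  `|K[i,j]|`, so a paralog may own a contig while ignoring groups it has
  no hits for.

Both are implemented and both are validated by the independent constraint
checker; the choice is exposed rather than hidden because the two
semantics genuinely disagree on real hit tables.

## Exact solving

Because the linking constraints force an all-or-nothing take of `K[i,j]`
once `C[i,j] = 1`, the integer program collapses to a purely combinatorial
search: pick at most one paralog per contig such that no two picks consume
the same `(j,k)`. `solve_pcap()` runs an exact depth-first
branch-and-bound over this space:

* contigs are partitioned into independent components (two contigs couple
  only if they share a positive `(j,k)` cell) and components are solved
  separately;
* within a component, contigs are explored in order of decreasing best
  contribution, candidate paralogs in order of decreasing value, and the
  bound is the current value plus the suffix sum of per-contig maxima;
* branches are pruned only when they cannot reach the incumbent within a
  tolerance of `1e-9`, so equal-objective ties are still visited and the
  lexicographically smallest assignment in `(contig, paralog)` index order
  wins. This makes outputs reproducible across runs and platforms.

The problem is NP-complete — `graph_to_pcap()` embeds graph 3-coloring,
with three identical queries as colors and one TCE type per edge — so
worst-case exponential time is unavoidable; the decomposition and bounds
make biologically structured instances (strong self-scores, sparse
cross-paralog hits) fast in practice. For decision-type reduction
instances the `mu` *objective weighting* is disabled (`mu_weight = FALSE`)
so that feasibility, not weighting, decides; the all-take constraint
itself keeps its strict form, which on reduction instances equals the
per-paralog form because all three queries are identical.

Sub-optimal alternatives (`enumerate_pcap()`) are produced by re-solving
with *no-good cuts* that exclude the complete `C` pattern of each
previously returned solution. Cutting on `C` rather than on `E` means
alternatives differ in paralog-to-contig structure, which is what a
curator wants to inspect; the method the original tool used for its
alternative solutions is not documented, so this is a design choice of
this package. The all-unassigned map is a feasible solution of objective
zero, so enumeration always terminates. A deliberately naive exhaustive
oracle (`brute_force_pcap()`) and an independent constraint validator
(`validate_assignment()`) guard the solver in the test suite; the oracle
enumerates complete contig-to-paralog maps and skips infeasible ones,
which is the only reading under which exhaustive search and the ILP
provably coincide.

## Hit processing

`parse_blast_tab()` and `parse_hmmer_domtbl()` read the two standard
tabular search outputs; query/model names carry the paralog and TCE number
as `<paralog>_<tce>` (last-underscore split, regex overridable).
Coordinates are 0-based half-open internally and converted at the I/O
boundary. Three filters mirror the intended workflow:

* **E-value** (`filter_evalue()`): strictly below a threshold, default
  `1e-5`. The strictness direction and the default are package choices —
  exposed as arguments — since only the existence of the filter is fixed
  by the workflow.
* **singletons** (`filter_singletons()`): a hit alone on its contig is
  suspicious; it must reach `min_norm_score` bits per aligned query
  residue to survive. Normalising the bitscore by aligned length is the
  simplest scale-free density and is our choice of normalisation. Note
  this filter is deliberately *not* concatenation-stable: whether a hit is
  a singleton depends on its contig's other hits.
* **TCE grouping** (`group_homologous_tces()`): when exon homology across
  paralogs is unknown, each paralog's exons are scored against all exons
  of the *same* paralog to form a background (those pairs are
  non-homologous by construction); a cutoff `mean + z * sd` per paralog
  separates genuine cross-paralog homology from promiscuous matches, links
  above the cutoffs of both members are drawn, and connected components
  become TCE groups. Components that would merge two exons of one paralog
  are flagged for manual review instead of silently merged; exons shorter
  than `min_len` residues (default 10) are excluded because short exons
  attract unstable scores.

## The simulator and what the benchmark does (and does not) show

The benchmark generator replaces an external sequence-evolution simulator
with an internal star-tree process so that the whole benchmark is
self-contained and seed-reproducible:

* an ancestral protein is drawn from BLOSUM-style amino-acid frequencies
  as a list of exons; exon lengths come from a log-normal (median 40
  residues ≈ 120 nt, sdlog 0.5) truncated to 15–300 aa. The truncation is
  intentional: micro-exons are a search-sensitivity problem, not an
  assignment problem, and including them would measure the wrong thing;
* each of the 8 paralogs evolves from the ancestor along a branch of 50
  PAM-like units (Poisson substitution events at `branch/100` per site,
  replacements drawn from the background; indel events at `indel_rate *
  branch` per site, length `1 + Geometric(1/2)`), realising ≈ 2.5% indels
  per sequence; each paralog exon then evolves independently into a query
  and a target species copy along branches of 20 units (≈ 1% indels).
  Substitution load is the free calibration knob; the indel fractions are
  the anchored quantities;
* fragmentation cuts each target paralog's exon list at independent
  breakpoints with probability chosen so the expected exons-per-fragment
  equals the requested level; fragments of different paralogs are never
  merged;
* scoring uses Smith–Waterman local alignment (Biostrings) with BLOSUM62,
  gap open 11 / extend 1, converted to bits with the gapped
  Karlin–Altschul constants (lambda 0.267, K 0.041), and an E-value cut
  `E = m * n * 2^-bits < 1e-4` emulating the search tool's filter. TCE
  scores depend only on the (query paralog, target paralog, exon) triple
  and full-length scores only on the (query, exon run) pair, so both are
  memoised across the replicated fragmentations of one family — the
  replicates re-randomise fragmentation, not sequence evolution, matching
  the benchmark protocol of evaluating both methods on the same simulated
  sequences.

Accuracy is per-unit: the fraction of fragments whose assigned (or
greedily picked) paralog is the true one, averaged over replicates; the
same metric is applied to both methods. For the greedy baseline, which
picks exactly one unit per paralog, the metric has a structural ceiling of
`n_paralogs / n_units` — at one exon per fragment that is 8/96 ≈ 0.083 —
which is precisely the collapse the benchmark is designed to expose.

What passing the benchmark does *not* show: the generator has no intron
structure, no codon-level evolution, no rate heterogeneity across sites,
no gene loss or secondary duplication, no assembly errors other than clean
fragmentation at exon boundaries, and no promiscuous hits from unrelated
domain families. Real hit tables are noisier in all these respects; the
benchmark isolates the assignment step under controlled divergence, it
does not certify end-to-end annotation accuracy on real genomes.

Default problem sizes: the packaged tests run 200 fragmentation replicates
per level at levels {12, 1}, and the reproduction script runs 200
replicates at levels {12, 8, 4, 2, 1}; both complete in minutes on one
CPU. The oracle-equivalence and constraint-validation suites use hundreds
to a thousand random instances of up to 6 contigs, 4 paralogs and 5 TCE
types, sizes at which exhaustive enumeration is still exact and fast.

## Post-processing

After solving, each paralog's contig set is classified
(`classify_locus()`): a single contig (case i); several contigs with
consecutive, non-overlapping TCE ranges, concatenated in TCE order with a
configurable N spacer and strand-normalised by reverse complement (case
ii); or a contig whose TCE set is ordered but gapped, with the gap's TCEs
on another assigned contig (case iii). Case-iii inserts go into the host
window between the closest flanking TCE hits: if the window contains a run
of three or more Ns (missing sequence at scaffold level), the *longest*
such run — leftmost on ties, a determinism choice since any locus in the
window preserves exon order — is substituted by the insert; otherwise the
insert is placed at the window midpoint padded with `flank_n` Ns (default
100; the padding size is not fixed by the workflow and is exposed). An
offset map relocates all host coordinates outside the edited window
exactly. Degenerate situations — hits out of TCE order along a contig,
overlapping ranges fitting no case, empty insertion windows, or
nested/cyclic interleavings — are flagged for manual review rather than
guessed at; re-running a spliced aligner over merged loci is left to
external tools by design.

## Known limitations

* The strict all-take semantics can leave a contig unassigned when the
  true owner genuinely lacks one of its TCE groups (a false-negative hit);
  the relaxed switch exists for exactly this case, at the cost of
  admitting partial owners.
* The number of paralogs is taken as given; an incorrect a-priori paralog
  count propagates into the assignment.
* Branch-and-bound worst cases are exponential; adversarial instances
  (e.g. large reduction graphs) are solvable only at desk scale.
* The greedy baseline is intentionally exon-blind; it is a comparison
  method, not a fallback.
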
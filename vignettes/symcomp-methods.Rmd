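---
title: "Methods: screening eroding symbiont genomes for complementarity"
author: "symcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening eroding symbiont genomes for complementarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symcomp)
```

## The problem

Aphids in several subfamilies host *di-symbiotic* nutritional systems: the
ancient primary endosymbiont *Buchnera aphidicola*, whose genome has eroded
to the point of losing whole vitamin pathways, plus a more recently
acquired co-obligate symbiont (often *Serratia symbiotica*) that completes
those pathways. Establishing that two such genomes form a metabolic unit,
and characterising how far each has decayed, reduces to a small set of
comparative-genomic operations:

1. decide, for every gene of a reference panel, whether a genome carries it
   **intact**, as a **pseudogene**, or not at all (**missing**);
2. evaluate biosynthetic-pathway completeness per genome and over the
   *union* of the consortium, allowing alternative enzymes for a step;
3. screen a virulence-factor panel at identity/coverage thresholds and
   summarise higher-level structures (flagellum, siderophore loci);
4. report erosion statistics (pseudogene fraction, genome size) and
   symbiont prevalence.

`symcomp` implements these stages as a tested pipeline, together with a
seeded synthetic genome-degradation generator so that every stage is
verifiable end to end without any download.

## Gene status: the ortholog length-ratio rule

Candidate coding sequences are matched to reference proteins by optimal
Smith–Waterman local alignment (BLOSUM62, affine gaps with opening 11 and
extension 1, the BLASTp defaults). Each CDS is assigned to at most one
panel gene — its best hit by score, with ties broken by identity and then
by gene name so that results never depend on panel order. A hit requires
identity ≥ 0.3 and reference coverage ≥ 0.1 per fragment; these floors are
deliberately permissive so that short pseudogene fragments remain
assignable, and are configurable via `classify_params()`.

A panel gene is then classified by the ortholog length ratio
$r = L_{query}/L_{ref}$ (amino acids):

* **MISSING** — no CDS assigned;
* **INTACT** — exactly one assigned CDS with $r \ge 0.8$ and no
  pseudogene annotation;
* **PSEUDOGENE** — otherwise: a single short fragment ($r < 0.8$; the rule
  is strict on the pseudogene side, so $r = 0.8$ exactly is intact), a CDS
  already annotated as disrupted (when `trust_declared_pseudo = TRUE`, the
  default), or a gene recovered in two or more fragments.

Two design points deserve emphasis. First, a gene split into several
pieces is a pseudogene *regardless of its cumulative aligned span*: a
coding region in two or more fragments is disrupted even if the fragments
jointly tile the reference. The longest single fragment sets
`length_ratio`. Second, a CDS whose best hit is another panel gene is not
allowed to rescue a second gene ("one CDS, one gene"), which prevents
paralog double-counting.

The coverage bookkeeping for fragments uses interval union on the
reference coordinate system (overlap counted once), so
`merged_ref_coverage` is monotone in added fragments and bounded by 1.

## Pathway completeness and complementarity

A pathway is an ordered list of steps; each step carries a non-empty set
of *alternative* genes able to perform it (e.g. the riboflavin phosphatase
step accepts yigB, ybjI or yigL). Over a set of genomes:

* a step is **SATISFIED** when any alternative is INTACT in any genome
  (those genomes are its *providers*);
* otherwise **PSEUDOGENIZED** when any alternative anywhere is a
  pseudogene — a pseudogenized alternative dominates a missing one, so a
  Ψ cell is reported whenever the function was visibly lost rather than
  never present;
* otherwise **MISSING**.

A pathway is **complete** only when every step is satisfied; no partial
score is reported, because the biological claim of interest is
qualitative. Consortium evaluation is the same boolean formula over the
union of members, hence monotone: adding a member can never un-satisfy a
step. Steps with exactly one provider are the points of metabolic
complementarity; steps with several providers are redundant.

The bundled catalog covers riboflavin, biotin, and the ten essential
amino acids with steps and alternative sets from the standard
enterobacterial biosynthesis repertoire. The engine, not the catalog, is
the contribution: any catalog can be supplied as YAML
(`read_pathway_catalog()`). One documented caveat: where a phosphatase
activity may be performed by enzymes whose identity is unknown, no
catalog can encode them; absence of all *known* alternatives is what the
engine reports.

## Virulome screening

Virulence factors are screened with presence thresholds of 50% identity
and 80% reference coverage (merged over fragments). A gene is **PRESENT**
when it passes both thresholds *and* is classified intact; **PSEUDOGENE**
when hits exist at or above the 30% detection floor but the gene fails
the length/fragment criteria or the presence thresholds; **ABSENT** when
nothing reaches the floor. Raising the presence thresholds can therefore
demote PRESENT to PSEUDOGENE but can never promote toward PRESENT
(anti-monotone), matching the caveat that absence calls are
threshold-dependent.

The flagellum verdict classifies the gene-level map into COMPLETE (every
flagellar gene present), ABSENT (none present), BASAL_BODY_ONLY, or
PARTIAL. BASAL_BODY_ONLY is defined as: at least one basal-body gene
present while hook and filament retain none. The definition is
deliberately not "all basal-body genes present": in a strongly eroded
genome the relic configuration retains a *subset* of basal-body genes
(e.g. flgB, flgH, fliE, fliM, fliN) while rod genes like flgC/flgF/flgG
may already be pseudogenized — that configuration is still a basal-body
relic, not a partial flagellum. The default gene-to-part map ships from
the standard enterobacterial flagellar regulon and is overridable.

Locus completeness (enterobactin *ent*, yersiniabactin *ybt*) is strict:
every locus gene PRESENT, otherwise the failing genes are listed.

## Erosion and prevalence statistics

Pseudogene percentages are rounded half away from zero to integer
percent, the convention used in published erosion tables (1258/2617 →
48%, 1172/3286 → 36%); full precision is retained in TSV output. Genome
sizes aggregate all replicons (plasmids included) and are reported in Mb
to two decimals, so a 3.05 Mb chromosome plus a 97.8 kb plasmid reports
3.15 Mb. When both an intact count and a pseudogene count are derivable,
the package reports its own consistent partition
(`n_cds_intact = n_cds_total - n_pseudogenes`) rather than reproducing
published tables whose rounding may disagree by one.

Prevalence uses the exact (Clopper–Pearson) binomial interval from
`stats::binom.test`; 97/97 positive colonies give 100% with a 95% CI of
about [96.3, 100]%.

## The synthetic degradation generator

`generate_reference_panel()` draws i.i.d. uniform-residue proteins with
lengths uniform in a range (default 100–300 aa, a realistic bacterial
protein-length band). `degrade_genome()` assigns each panel gene an
independent fate — deleted, truncated, fragmented, or intact — with
default probabilities 0.2/0.3/0.1 (residual 0.4 intact), the regime used
for the recovery benchmark. Design choices:

* **Truncation fractions** default to uniform(0.2, 0.6), bounded away
  from the 0.8 classification threshold by a margin of 0.05 so ground
  truth is unambiguous; a separate `boundary_stress` mode truncates at
  exactly 0.8 to pin the strict-inequality contract.
* **Fragmentation** partitions a contiguous 65–95% span of the protein
  into 2–4 pieces, each at least ~11% of the reference, so every
  fragment stays above the per-fragment coverage floor and the
  multi-fragment rule is what is being tested.
* **Point substitutions** at rate 0.05 per site keep simulated identities
  (~95%) far above the assignment floor.
* Emitted genomes carry real nucleotide sequence: proteins are
  back-translated with uniform codon choice under the bacterial genetic
  code (table 11) plus a terminal stop, placed with random spacers and
  strands on a single replicon, and written as GFF3+FASTA or a GenBank
  flat file that parses back identically. Frameshifts are *not*
  simulated — the classification rule is length-based, so a frameshift
  would manifest as truncation anyway.

What the generator does not emulate: phylogenetic sequence evolution
(substitutions are uniform, no rate heterogeneity or indels), realistic
codon usage, operon structure, paralogous families, or assembly and
annotation error. Passing the recovery benchmark therefore demonstrates
that the classification logic implements its rule correctly, not that
the thresholds are optimal for any particular real genome pair.

`simulate_consortium()` engineers two genomes in which each scheduled
pathway step is intact in exactly one assigned member (the other member
receives a deletion or a sub-threshold truncation), so consortium
verdicts and provider attribution can be checked against a known design.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; GFF3 (1-based inclusive)
  and GenBank locations are converted on read, and compound (joined)
  locations are flattened to outer bounds — intron-aware handling is
  unnecessary for bacterial genomes.
* Translations prefer an embedded `/translation` qualifier; otherwise
  they are derived from the genome sequence (table 11,
  `no.init.codon = TRUE` so internal fragments are not forced to start
  with Met), trimming the terminal stop and recoding internal stops of
  declared pseudogenes as X.
* Identity is identical positions over all alignment columns of the
  optimal local alignment. Where several co-optimal alignments exist
  (common for unrelated sequences), identity is a property of the chosen
  traceback; the alignment *score* is the well-defined quantity, and the
  test suite pins identity only on homologous pairs where the optimum is
  unique.
* Zero CDS genomes: every panel gene reports MISSING; pseudogene
  percentage of an empty CDS set is n/a, not 0.
* Tie-breaks everywhere are content-based (score, then identity, then
  lexicographic gene name), making all outputs invariant to input order.

## Problem sizes used by the test suite

The bundled checks run a 200-gene degradation benchmark (lengths
100–300 aa) for fate recovery, 50 seeded pairs against a quadratic
dynamic-programming alignment oracle, and exhaustive boolean-oracle
comparison over random pathway instances up to 4 genomes × 10 steps × 3
alternatives — sizes at which the independent oracles are exact and the
whole suite completes in a couple of minutes on one CPU.

## Known limitations

* The GenBank reader supports the conventional LOCUS/FEATURES/ORIGIN
  flat-file subset emitted by standard prokaryotic annotation pipelines;
  exotic location operators (`order()`, remote accessions) are not
  handled.
* The pseudogene rule is purely length-based plus declared flags; it
  does not detect frameshifts or internal stops from the nucleotide
  signal itself.
* Secretion-system detection and prophage prediction are out of scope;
  autotransporters and toxins enter the virulome screen as ordinary
  panel genes.
* Reciprocal-best-hit verification against a full query proteome is
  intentionally not required for panel screening (the panel is
  one-directional); an eroded genome rarely has a competing full-length
  paralog, and the one-CDS-one-gene rule already prevents double
  counting.
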
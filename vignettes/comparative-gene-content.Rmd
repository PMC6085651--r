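---
title: "Comparative gene content of mycoheterotrophic plants: models and methods"
author: "MycoLoss authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative gene content: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MycoLoss)
```

# The scientific problem

Mycoheterotrophic plants have lost photosynthesis and obtain carbon from
fungi. Their nuclear gene content, read off assembled transcriptomes, should
show (i) depletion of photosynthesis-related functional categories relative
to photosynthetic relatives, and (ii) parallel losses across independently
evolved heterotroph lineages. Both claims are statistical: transcriptome
assemblies miss genes for technical reasons (low expression, assembly
quality, contamination), so the analysis must filter aggressively, compare
species group-wise, and quantify how surprising the observed parallelism is
under a null of independent losses.

MycoLoss implements this analysis and a synthetic-data generator that
emulates its inputs, so every stage has planted ground truth to test
against.

# Post-assembly filtering

Four filters are applied per species, in order:

1. **Major isoforms.** For each gene the isoform with the most mapped reads
   is kept; ties go to the lexicographically smallest transcript id (a
   deterministic convention — read counts are real-valued and ties are
   essentially simulation artifacts).
2. **Coverage.** Transcripts with mean coverage below 3 reads/position are
   dropped. The threshold is inclusive: coverage exactly 3 is kept.
3. **CDS selection.** All six reading frames are scanned for stop-free
   codon stretches; 5'-partial stretches running from the frame start to
   the first stop are allowed. A stretch qualifies at ≥ 30 amino acids, or
   at any length when it overlaps a supplied protein-domain hit (domain
   rescue also applies below 30 aa — the conservative reading, flagged in
   the output via `has_domain`). The longest qualifying stretch wins; ties
   prefer the plus strand, then the lower frame, then the smaller start,
   so results are order- and strand-enumeration-invariant. Coordinates are
   1-based inclusive on the forward transcript, stop codon excluded.
   `five_prime_complete` is `TRUE` when the stretch contains an in-frame
   ATG whose upstream context is credible: the stretch begins after an
   in-frame stop, or at least 3 nt of transcript precede the ATG. A
   maximal stretch can begin before its initiator ATG, so completeness is
   judged at the first in-frame ATG rather than at the stretch boundary.
   Codons containing `N` are treated as non-stop.
4. **Taxonomy.** Each CDS's BLAST-style hits (e-value ≤ 1e-5) are reduced
   to the best bit score; a lineage containing *Streptophyta* means plant,
   anything else means contaminant, and no hits at all means plant
   (absence of a database match is not evidence of contamination). If
   several hits tie at the top score and any is plant, the CDS is kept —
   the tie rule favours retention, consistent with retaining no-hit
   sequences.

Gene expression is summed FPKM over all isoforms of the retained genes.
1–1 orthologs are reciprocal best hits with strict uniqueness: a query
whose best bit score is attained by two subjects yields no pair, because a
"1–1" relation cannot be established from an ambiguous best hit.

# Group-wise enrichment

Direct gene-to-term annotations are closed under ancestry on the `is_a`
DAG ("paternal" terms), because a gene annotated to a leaf belongs to every
more general category on the way to the root. Organelle-encoded genes
(1–1 orthologs of plastid/mitochondrial genes) are removed first — the
question is about nuclear gene content.

For one clade with heterotroph set $H$ and autotroph set $A$, and for each
term $t$ and pair $(h, a) \in H \times A$, a two-sided Fisher exact test
compares $[c_{th}, n_h - c_{th}; c_{ta}, n_a - c_{ta}]$, where $c$ are
genes with the term and $n$ the number of genes with any term. A term is
skipped for a pair only when both species have zero genes with it; a zero
in one species is exactly what a total loss looks like and remains
testable. The two-sided p-value is the sum of hypergeometric point
probabilities not exceeding the observed one (relative tolerance 1e-7 for
ties), the convention of mainstream implementations.

Pairwise results are aggregated per term with an intersection-style
Bonferroni rule: if all pairs shift the same way,
$p_{\text{group}} = \min(1,\ n_{\text{pairs}} \cdot \max_i p_i)$,
otherwise the term is "mixed" and $p_{\text{group}} = 1$. This is the
strictest of the defensible aggregations (the alternative
$n \cdot \min_i p_i$ is available via the `aggregate` argument); it makes a
group-level claim only when every heterotroph differs from every autotroph
in the same direction, which is what "under-represented in the group"
should mean. The max-rule also makes $p_{\text{group}}$ a valid p-value
for the intersection null.

Across terms, q-values use Benjamini–Yekutieli rather than
Benjamini–Hochberg because propagated counts on a DAG are strongly and
positively-and-negatively dependent (a child's genes are a subset of its
parent's); BY controls the FDR under arbitrary dependence at the cost of
the $c(m) = \sum_{k\le m} 1/k$ inflation. BY is applied once per clade
across all tested terms, not per direction.

The effect size mirrors the published convention: the median over
$H \times A$ pairs of the ratio of fractions
$(c_{th}/n_h)/(c_{ta}/n_a)$. Pairs with zero counts in both species are
skipped; a positive heterotroph fraction against a zero autotroph fraction
contributes $+\infty$; with an even number of ratios the median is the
mean of the central two, reported as $\infty$ when either central element
is infinite.

# Loss parallelism

The background is the core gene set: genes with a 1–1 ortholog in the
reference proteome that are present in **every** autotroph. This
conditioning removes assembly-quality and lineage-specific artifacts from
the denominator. For two heterotrophs with loss sets $A, B \subseteq$ core
(size $N$):

$$\text{overlap\%} = 100\,\frac{|A \cap B|}{\max(|A|,|B|)}, \qquad
  \text{expected\%} = 100\,\frac{|A||B|/N}{\max(|A|,|B|)}
                    = 100\,\frac{\min(|A|,|B|)}{N}.$$

The larger-set denominator is the package's documented convention: it is
the only denominator under which the published per-pair expectations are
mutually consistent at roughly 16%. Significance is the upper tail
$P(X \ge |A\cap B|)$ of $X \sim \mathrm{Hypergeom}(N, |A|, |B|)$, evaluated
through the log-space tail of the distribution so that $\log_{10} p$ is
accurate to at least $-500$ — observed parallelism produces p-values far
below double-precision underflow. Shared-loss counts quoted only as
percentages are reconstructed by rounding to the nearest integer.
Transcriptome-based absence is weaker evidence than genome-based absence;
the pipeline surfaces this as a report footnote rather than modelling it.

# Targeting reconciliation

Two predictor styles are reconciled per protein variant. A TargetP-style
call is accepted when its reliability class is ≤ 4 (class 5 means "no
transit peptide"); a DualPred-style call indicates dual targeting at score
≥ 0.5. An accepted plastid/mitochondrial call plus a dual call is a
non-contradictory dual prediction; agreement on one compartment returns
that compartment (secretory agrees with the dual-style "other"); an
accepted call contradicted by the other tool is contradictory. Support
from only one tool (e.g. class 5 against a plastid or dual call) is also
labelled contradictory rather than accepted — the cautious reading; a
config flag could relax this but the default mirrors conservative
reporting.

Alternative translation starts can expose a second transit peptide, so
proteins are additionally truncated at the first methionine after the
first 25 residues (1-based position ≥ 26, the Met retained as the new
initiator) and isoform variants are scored as well. The protein-level
verdict takes the highest-precedence variant verdict with precedence
dual > plastid > mitochondrion > secretory > contradictory > none. The
precedence is a package convention (different variants of one protein can
genuinely support different compartments; the supporting variant is
recorded so users can inspect conflicts). Dual ranks highest because it
subsumes plastid import capability, which is the question asked of
substitute candidates: a nuclear protein can only replace a plastome-lost
ribosomal protein if it can be imported, so candidates (HMM family hits at
e ≤ 1e-5, excluding 1–1 orthologs of the plastid gene itself) are flagged
import-capable for plastid/dual verdicts and single-tool for contradictory
ones.

# Selection shifts

The package consumes precomputed branch-model likelihoods. The LRT
statistic is $2(\ln L_{\text{free}} - \ln L_{\text{constrained}})$ against
$\chi^2_{df}$; $df$ defaults to the parameter-count difference and to 1
when counts are absent (two-ratio vs one-ratio contrasts differ by one
parameter). Slightly negative differences are optimizer artifacts and are
clamped to zero with a warning. P-values are floored at 1e-300 to keep
downstream logs finite; Bonferroni $m$ is a configurable input because the
relevant gene set (for example a 5-gene pathway) is an analysis decision.
Fits with synonymous branch rates above 0.5 are flagged as saturated but
not corrected. A significant, higher heterotroph dN/dS is "relaxed"; a
significant, lower one "intensified".

# The synthetic-data generator

The generator is first-class, tested code. It emulates one clade under a
single integer seed (per-stage streams are derived from it, so identical
seeds give byte-identical outputs):

* **Study design.** 2 heterotrophs × 3 autotrophs by default, mirroring a
  two-heterotroph-lineage comparison against three photosynthetic
  references; 2000 genes; a 150-term, depth-5 `is_a` DAG with 8 planted
  photosynthesis-like leaf terms. The published study's second clade is
  obtained by running the generator again.
* **Annotation.** Each gene draws 1–4 direct terms. Planted leaf terms
  receive 3× sampling weight so each is a ~4%-of-genes category — in real
  plant annotations photosynthesis/plastid categories are large gene sets
  (single terms covering 1–10% of annotated genes), and the group-wise
  test is meant to operate in that regime.
* **Loss model.** A gene annotated to a planted term is lost in a
  heterotroph with probability 0.9, others with 0.1. With probability
  `shared_loss_frac` (0.6) a gene's loss indicator is drawn once and
  shared by all heterotrophs; otherwise independently per heterotroph.
  This one parameter controls exactly the overlap the hypergeometric test
  detects: at 0 the test's p-values are uniform, at 1 losses coincide.
* **Transcripts.** `1 + Poisson(0.7)` isoforms per present gene;
  negative-binomial reads (mean 200, size 5 — heavy-tailed like RNA-seq);
  log-normal coverage (`meanlog = log 20`, `sdlog = 1`, so a realistic
  minority of transcripts falls below the coverage-3 filter); every
  transcript carries a planted 40–80-codon ORF between short UTRs. 20% of
  transcripts are contaminants from a small fixed fungal/bacterial
  taxonomy shipped as a text fixture.
* **Hit tables, targeting, fits.** Best hits carry the true source
  lineage (`hit_noise` flips kingdoms; 5% of plant transcripts get no hit
  and must be retained by the no-hit rule); directional ortholog tables
  make true pairs mutual best hits except a `rbh_corruption` fraction;
  targeting rows are consistent with planted signals (reliability classes
  for supported signals drawn from a fixed 0.4/0.3/0.2/0.1 mixture over
  classes 1–4); likelihood fits draw central $\chi^2_1/2$ gains under the
  null and noncentral gains plus elevated dN/dS for a relaxed fraction.
  The noise knobs default to 0: the generator's baseline is a clean
  oracle, and tests switch individual noise sources on explicitly.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: sequence evolution and alignment error, biased
assembly loss correlated with expression level, annotation transfer error
(every gene's annotation is exact), ontology misannotation, compositional
biases in BLAST bit scores, and polyA-selection artifacts that inflate
mobile-element categories in real comparisons. Results on real data
additionally depend on database versions, which is why published term
counts are not reproduction targets.

# Numerical choices and degenerate inputs

* Fisher: point-probability two-sided sum over the hypergeometric support
  via `dhyper`, tie tolerance 1e-7; degenerate margins return 1.
* Hypergeometric tail: `phyper(log.p = TRUE)`; inputs validated against
  $0 \le k \le \min(K, n) \le N$.
* BY: `p.adjust(method = "BY")`; inputs outside $[0,1]$ are errors.
* A species with no annotated genes after organellar exclusion aborts the
  clade's enrichment with an explicit error rather than emitting empty
  tables.
* Empty loss sets make the overlap undefined and raise an error; $k = 0$
  gives $p = 1$.
* All tie-breaks (isoforms, ORFs, taxonomy, RBH) are deterministic and
  documented above, so shuffled inputs give identical outputs.

# Problem sizes used by the test-suite simulations

Module tests use 40–500-gene configurations; the end-to-end enrichment
properties use the full default conditions (2000 genes, 150 terms) over
50 seeds for planted-signal recovery and 200 seeds for null FDR control;
oracle equivalences are exhaustive over all 2×2 tables with margins ≤ 12
and hypergeometric designs with $N \le 60$. These sizes were chosen so the
whole suite exercises the default study conditions while remaining quick
to run on a laptop.

# Known limitations

* The enrichment's intersection-Bonferroni aggregation is conservative by
  design; weak but consistent depletion across pairs can be missed.
* The overlap denominator convention (larger set) is one of several
  defensible readings; it is configurable in spirit but fixed as the
  package default.
* Transcriptome absence conflates loss with non-expression; the package
  reports, but does not model, this caveat.
* The targeting precedence resolves inter-variant conflicts by fiat;
  inspect `supporting_variant` when a verdict matters.
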
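---
title: "Predicting phage tRNA insensitivity to host anticodon nucleases"
author: "phanticodon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting phage tRNA insensitivity to host anticodon nucleases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phanticodon)
```

## The biological question

Anticodon nucleases are bacterial toxins that cut specific tRNAs inside the
anticodon loop, depleting the tRNA pool as an early, translation-stalling
response to phage infection. Phage genomes — particularly tRNA-rich virulent
phages — often carry their own copies of host tRNAs. If those copies differ
from the host's at the nuclease cleavage site, they survive the cut and can
sustain phage translation while the host pool collapses. For isoacceptors cut
*inside the anticodon itself*, a cleavage-site mutation would change the
tRNA's decoding identity, so the evasion route available to the phage is to
not encode that isoacceptor at all.

The package turns these two predictions into machine-checkable calls over a
host tRNA set, a collection of phage tRNA sets, and a catalog of nuclease
target specificities, and it implements the alternative-hypothesis check
(codon compensation) as codon-usage statistics.

## The anticodon-arm model

A tRNA anticodon arm is modelled as the canonical geometry: a 5-bp stem
closing a 7-nt loop. Loop positions are indexed 0–6, corresponding to
standard tRNA numbering 32–38, with the anticodon at loop indices 2–4
(positions 34–36). Expanded 8–9-nt loops (some suppressor tRNAs) are
deliberately rejected with an "arm not found" error rather than guessed at.

`find_anticodon_arm()` scores candidate placements by the number of paired
stem positions, counting Watson–Crick pairs and the G:T wobble (common in
real tRNA stems; excluding it would reject valid host genes). With an
anticodon hint, every occurrence of the hint (including overlapping
occurrences) is a candidate with the hint at loop 2–4, and candidates pairing
at ≥ 3 of 5 positions are kept; without a hint all placements are scanned and
the threshold rises to 4, trading recall for specificity when nothing anchors
the search. Ties are broken by proximity of the loop start to 0.42 × gene
length — the anticodon-loop position of a canonical ~76-nt tRNA — then by the
smaller coordinate, making the search fully deterministic. The finder is
tested for exact agreement with an independent exhaustive brute-force search
on hundreds of randomly planted arms.

## Sensitivity calls

Each phage tRNA is matched to a host counterpart: exact (isotype, anticodon)
key match when possible, otherwise the same isotype at smallest full-sequence
edit distance, flagged as an isotype-level match rather than dropped —
anticodon-shifted phage tRNAs are precisely the interesting evasion
candidates. Among several host copies the smallest edit distance (then the
lexicographically smallest gene id) wins, deterministically.

The cleavage site of a catalog entry resolves to loop indices as follows:

* integer bond *b* (0–5): the two flanking indices {b, b+1};
* a dinucleotide motif (e.g. the serine GA site): all loop positions covered
  by occurrences of the motif in the **host** loop;
* the `anticodon` sentinel (cut inside the anticodon, exact bond
  uncharacterised): the anticodon window {2, 3, 4}.

A phage/host loop pair then yields `mutated_at_cleavage_site` (some
difference hits a cleavage-site index), `mutated_in_loop` (differences only
elsewhere in the loop — the loop is just 7 nt, so no finer distance cutoff is
meaningful), or `loop_identical`. For modification-dependent nucleases
(Colicin E5 requires a modified wobble base the sequence cannot show), any
non-identical loop is reported as `modification_dependent_unresolved` instead
of asserting cleaved or uncleaved. These are predictions about sequence, not
biochemistry: a mutated loop is *predicted* insensitive; the recognition
determinants of several nucleases are unknown, and the package cannot
distinguish recognition-site from cleavage-site mutations.

Prevalence is presence/absence per phage (copy number ignored), and avoidance
lists isoacceptors cut within the anticodon, calling them avoided at
prevalence ≤ 0.05 of the collection by default. The threshold is a
configurable operationalisation of "rarely encoded"; at the default it means
"absent, or present in at most 1 of 20 phages".

## The nuclease catalog

Target specificities live in data, not code: a TSV with one row per
(nuclease, isoacceptor) giving the cleavage bond, optional motif and a
modification-dependence flag, loaded by `load_catalog()` and freely editable.
The two shipped fixtures encode only well-established main-text-level facts
(VapC cutting serine isoacceptors at the GA site within the anticodon; PrrC
and tRNA-Lys(ttt); VapC-LT2 and initiator fMet; Colicin D's arginine
wildcard; Colicin E5's modification-dependent Tyr/His/Asn/Asp set; RelE's
listed targets). Two caveats are flagged in the fixtures' citation notes
rather than silently corrected: the RelE target list includes Gln(cga) as
catalogued even though the anticodon cga would not decode a glutamine codon,
and Colicin D's exact loop bond is not stated by the sources the fixture
follows, so its row carries bond 5 (the 3'-most loop bond) with a note.

## Codon-usage arm

`count_codons()` reproduces `cusp` semantics: per-codon count, fraction among
synonymous codons, and frequency per 1000 codons, under the bacterial genetic
code (translation table 11, whose codon→amino-acid map equals the standard
code). The quantity compared by both t-tests is the per-1000 frequency —
length-normalised, and exactly cusp's "frequency" column. Codon→tRNA mapping
is the strict reverse complement with no wobble expansion: reproducible and
conservative, at the cost of understating the decoding reach of a repertoire.
Stop codons stay in the tables but are excluded from preferred-codon
concordance ("per amino acid") and from the decoded/non-decoded comparison.

`welch_t_test()` and `paired_t_test()` are implemented from the standard
formulas (Welch–Satterthwaite degrees of freedom; one-sample t on paired
differences) and verified against R's reference implementation to 1e-8.
Degenerate inputs — zero variance in both groups, or identical pairs — raise
a typed error that the pipeline layer records in `stats.tsv` instead of
crashing the run.

## What the synthetic generator emulates — and what it does not

A scenario states a world: host isoacceptor keys, targeted keys with their
cleavage specs, avoided keys (which must be anticodon-targeted), the loop
index each targeted copy mutates, and codon-weight profiles for two CDS
groups. The default scenario is 12 host isoacceptors, 6 targeted of which 4
carry planted cleavage-site mutations (at loop indices outside the anticodon,
so isoacceptor identity is preserved) and 2 — serine keys cut at the GA site
within the anticodon — are omitted from every phage; 20 phages; identical
uniform codon profiles (a true null) with 40 CDS of 300 nt per group.

Generated genes are 76 nt with a perfectly paired planted stem at loop start
31 (0.41 × length), flanks re-drawn until the anticodon occurs exactly once
so recovery is unambiguous by construction. Genes are embedded in a synthetic
genome record with spacers, alternating strands, and a tRNAscan-SE-dialect
annotation table, so the file-based pipeline exercises the same I/O path as
real inputs. Generation is a pure function of the scenario: one seeded
sub-stream per object, derived from stable labels, so adding a phage never
perturbs earlier phages, and repeated runs are byte-identical. The planted
mutation is the cyclic successor base (A→C→G→T→A), checkable by eye.

What a green test establishes is therefore that the pipeline recovers a
*planted* evasion pattern exactly — classification, prevalence and avoidance
logic, I/O round-trips, determinism. It does not establish anything about
real phage collections: the generator has no phylogenetic correlation between
phages, no annotation noise, no expanded loops or introns, no base
modifications, and flat (not genome-like) base composition. One structural
artifact is worth knowing: because generated CDS sets share length and count,
and every CDS is forced to start ATG and end TAA, the per-1000 frequencies of
two generated tables sum to the same constant over sense codons, so the
paired phage-vs-host test on such fixtures has mean difference exactly zero
(t = 0, p = 1). Real gene sets, with varying lengths, do not have this
property.

## Numerical and design choices

* DNA alphabet throughout (U→T on read); anticodons lowercase in keys, as in
  the field's isoacceptor notation `Ser(gct)`.
* tRNAscan-SE coordinates (1-based inclusive, begin > end = minus strand) are
  preserved at the file boundary and converted to sense-strand sequences
  internally. One annotation dialect is supported; arm finding on raw FASTA
  covers unannotated inputs.
* Arm search thresholds (3 of 5 with hint, 4 of 5 without) and the 0.42
  positional prior are fixed, documented tie-breaks, not tunables.
* Edit distance for counterpart matching is plain Levenshtein on the full
  gene sequence.
* The type-I error of the decoded/non-decoded Welch comparison is checked
  empirically over 1000 null replicates of the synthetic codon-group
  comparison (acceptance suite); the multinomial coupling between codon
  counts makes the test only negligibly conservative at the default sizes.
* Genes whose arm cannot be resolved are skipped with a reason row, never
  silently dropped: genes in = calls + skips.

## Limitations

Calls are sequence-level predictions of insensitivity, not cleavage assays.
Wildcard catalog rows expand only over isoacceptors the host actually
encodes. The avoidance threshold, like the "rarely encoded" notion it
operationalises, is a convention; reviewers should read `avoidance.tsv`
alongside the prevalence table rather than the boolean alone. Wobble-aware
codon→tRNA mapping is reserved as a future switch; with strict mapping, the
decoded-codon group is smaller than a wobble-aware analysis would make it.
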
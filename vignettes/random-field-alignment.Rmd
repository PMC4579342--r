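---
title: "Random-field alignment of shallow read clouds: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-field alignment of shallow read clouds: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Read-cloud (linked-read) protocols dilute long DNA fragments (around 10 kb)
into wells so that each well receives only a small fraction (~1-2%) of the
genome, then barcode and short-read sequence each well shallowly
(`C_R` around 1.5x per fragment). Reads sharing a well that map close
together form a *read cloud* — the footprint of one hidden long molecule.
Two coverage numbers describe such a design: `C_F`, genome coverage with
long fragments, and `C_R`, short-read coverage of each fragment; total
sequencing depth is `C = C_F * C_R`.

Segmental duplications (>5 kb at >94% identity) defeat conventional
short-read alignment: a read maps equally well to several copies and its
mapping quality collapses. But the reads of one cloud all come from *one*
copy. Scoring entire clouds against candidate copies — rather than reads in
isolation — recovers unique placements wherever the copies differ at sites
covered by any read of the cloud.

## The model

Each well is modelled as a set of hidden long molecules
`M_c = (L_c, X_c, lambda_c, B_c, S_c, E_c)`: location, hidden sequence,
read density, end-marker pair, size, and an existence indicator
`E_c ~ Bernoulli(p_e)`. Reads `R_n = (o_n, A_n)` carry observed bases and
qualities `o_n` and a hidden alignment `A_n` restricted to a seeded
candidate domain. The joint probability of a well factorises over
molecules,

```
P(R) = prod_c sum_{M_c} P(M_c) P(R_c | M_c),
```

so each candidate molecule induces one potential over the reads assigned
to it, and alignment becomes MAP inference over a Markov random field whose
variables are the per-read alignment choices (including "unassigned").

The molecule prior decomposes as
`P(E) P(B, S, lambda | E) P(L | E) prod_l P(X_l | E)` with:

* `P(L | E=1)` uniform over the usable genome (`1/G`);
* `P(X_l | E=1)` categorical with mass `1 - theta` on the reference base
  and `theta/3` on each alternative — `theta` is a single shared SNP-rate
  parameter (default `1e-3`, the germline SNP rate in unique regions);
* `P(B) P(S, lambda | B)`: an empirical table over the four end-marker
  states and, per state, a 2-D Gaussian kernel density estimate over
  `(log S, log lambda)` learned from uniquely mapped training clouds.
  Size and density are learned jointly per marker state because clouds
  with visible end-markers are systematically longer and denser.

The emission `P(R_c | M_c)` for an active molecule is the standard shotgun
model: read count `~ Poisson(lambda * S)`, read starts uniform (`1/S`
each), and each base emitted from the hidden sequence `X` with
quality-derived error probability `e_b = 10^(-q_b/10)` (probability
`1 - e_b` of the true base, `e_b/3` each alternative). Candidate alignments
containing indels contribute a fixed `log(1e-4)` penalty per event: `X`
models substitutions only. A read may instead be *off-target*
(contaminant/artefact) with probability `1e-5`; crucially, the off-target
hypothesis still has to emit the read's bases, under a uniform background
(`(1/4)^L`). Without that background term the unassigned state would be
absurdly cheap — a single sequencing error would outweigh it — and the
comparison between "this molecule emitted the read" and "something else
did" would not be likelihood-to-likelihood.

### Variable elimination

The potential `phi_c(R_c) = sum_{M_c} P(M_c) P(R_c | M_c)` is computed in
time linear in aligned bases:

* `X_c` is eliminated position by position: each covered position
  contributes `sum_x pi(x) prod_{reads covering it} P(obs | x)` over the
  four bases; uncovered positions contribute exactly 1. Unanimous
  disagreement of several reads at one position therefore pools into a
  single SNP-like cost (`~ theta`), which is what lets a cloud embrace a
  true variant while still rejecting the wrong repeat copy.
* `lambda_c` is eliminated by numeric quadrature on a 64-point log-spaced
  grid spanning the 1st-99th percentile of training densities, with
  trapezoid weights, against the KDE and the Poisson count term. The KDE
  factor is memoised on ~3% log-size bins (the Poisson factor always uses
  the exact size).

`E_c`, `B_c`, `S_c` and `L_c` collapse to single values given an
assignment: `E_c` is 1 iff any read is assigned, `B_c` is read off the
assigned end-marker reads (a marker read within one read length of the
span boundary claims that end), and `S_c` is the assigned span (floored at
one read length). An inactive molecule scores exactly `log(1 - p_e)`.

## The pipeline

1. **pass 1** — every read is aligned to the full reference, best hit only.
2. **Cloud seeding** — single-linkage clustering of pass-1 starts with a
   3.5-kb gap and a six-read minimum yields candidate clouds; an interior
   end-marker read that splits a cloud into two viable halves does so.
   Contigs are cut from the reference with 1 kb padding on each side
   (reads of the true fragment can precede the first clustered read) to
   form the *abbreviated reference*, with a bidirectional coordinate lift.
3. **pass 2** — reads are realigned to the abbreviated reference allowing
   multiple hits; each read's domain is capped at 15 alignments by
   descending score (ties: leftmost contig/offset, forward strand first).
   Reads that exceeded the cap are flagged high-copy, excluded from
   potentials, and reported with MAPQ 0 — such reads carry almost no
   placement information and would only blur other reads' potentials.
4. **MAP inference** (below).
5. **Queries** — per-read posteriors/MAPQ, per-cloud quality, existence
   posteriors, collision and low-quality exclusion flags; output as a
   lifted SAM plus a cloud BED.

The built-in mini-mapper (exact 31-mer seeds at three offsets per
orientation via Aho-Corasick matching, ungapped extension with at most five
mismatches) serves desk-scale references; external aligner output in the
same multi-record SAM dialect can be substituted at either pass. Pass-1
ties are broken by a seeded deterministic hash, which spreads exact-repeat
reads across copies the way a production aligner's randomized best-hit
reporting does, while keeping every run reproducible.

## MAP inference

The joint assignment space factorises only through the molecule potentials,
so we use local search with exact small-case handling:

* **Exact mode** — if the number of joint states `prod_n (K_n + 1)` is at
  most `exact_cap` (4096), depth-first enumeration with incremental
  rescoring finds the global MAP. Tiny wells and unit tests take this
  path.
* **Local search** — otherwise: greedy initialisation (each read at its
  best aligner-score hit), then iterated-conditional-modes sweeps in
  random order (change one read's alignment or unassign it, accept iff the
  objective rises), interleaved with whole-cloud block moves (relocate the
  movable subset of a molecule's reads into another molecule, or dissolve
  the molecule entirely) and, when a sweep stalls, pair-escape moves (one
  tentative move plus the best compensating move among reads of the two
  affected molecules). The first of `restarts = 3` runs starts greedy;
  later runs perturb a random 30% of reads to diversify. The best
  objective wins; ties keep the earlier run.

Every accepted move increases the objective, so the score trajectory is
monotone and the returned assignment is a local maximum under single-read
moves (asserted in the tests). Incremental rescoring updates only the
columns a moved read covers; a version counter per molecule lets converged
reads be skipped until a neighbouring molecule changes. Determinism:
identical input and seed give bit-identical assignments.

## Confidence queries

**Read posterior.** After convergence, interactions are local:
`P(R_n) = P(R_n | R_{l-} = r_MAP)` where `R_{l-}` are the reads that do not
share covered positions with read n's candidates. If the local read set is
small (at most `cap_local = 12` reads and at most 256 joint states), the
neighbourhood is marginalised jointly with read n; otherwise neighbours are
fixed at MAP (the same approximation direction, one step further). The
256-state cap on the joint path exists because enumeration cost is the
product of local domain sizes, not their count; past it the fixed-neighbour
value is indistinguishable in practice. Options that lift to the same
genome position — overlapping padded contigs regularly duplicate a
placement — are one hypothesis and their mass is pooled. The posterior of
the MAP placement converts to MAPQ as `round(-10 log10(1 - p))` capped at
60; the standard MAPQ >= 10 filter corresponds to 90% confidence.

**Cloud quality** is `log P(R_c)` at the MAP read set — the same
variable-elimination computation — and decreases by a bounded,
theta-dependent amount per implied variant. Clouds falling below the 1st
percentile of a per-well null (reads' base columns shuffled within coarse
quality strata, 3 replicates by default) are flagged low-quality:
they likely belong to a copy not present in the reference.

**Existence posterior.** A read can be unique within its molecule while
the *whole cloud* could sit equally well in an inactive candidate
elsewhere. Enumerating whole-cloud placements into every inactive molecule
that can host all member reads (same-locus contig twins excluded — they are
the same hypothesis) and softmax-renormalising gives
`P(E_c | rest)`; molecules below 0.9 are marked excluded, mirroring the
MAPQ-10 convention. Emitted read confidence multiplies the read-level
posterior by this molecule-level posterior, since a placement cannot be
right if its cloud is elsewhere; the two queries remain separately
available.

**Collisions.** Two fragments of one well overlapping in the genome merge
into one cloud and their reads cannot be attributed; the chance is roughly
the well genome fraction (~2%). With end-marker efficiency `p = 0.77` and
independent markers, at least one interior marker reveals the join with
probability `1 - (1 - p)^2 = 0.947` — the familiar ~95% figure. (The
literal expression `1 - p^2` evaluates to 0.41; the detector reports both
numbers rather than choosing silently.) Flagged clouds are excluded from
variant-ready output.

## The simulator

`make_repeat_genome()` plants segmental-duplication pairs (default: ten
pairs of 5-20 kb at 94-99% identity in a 5-Mb uniform-random genome,
mirroring the size/identity definition of recent segmental duplications)
by copying source intervals to non-overlapping destinations and mutating
them by uniform substitution. `simulate_well()` draws fragments uniformly
(log-normal sizes, `meanlog 9.2`/`sdlog 0.3`, mean ~10.4 kb) until the well
holds its 2% genome fraction — the crossing fragment is kept with
probability proportional to the shortfall so realised coverage is unbiased
— then lays a read stencil over each fragment: Poisson read count with mean
`C_R * S / read_length`, uniform offsets, first/last slots carrying an
end-marker flag with probability 0.77 each. With probability
`collision_rate` (default 0.02, the per-well genome coverage) a fragment
is deliberately placed overlapping an earlier one. Base qualities follow a
first-order integer chain mean-reverting to a plateau-then-decay profile
(Q35 to Q25); substitutions occur per base with probability
`10^(-q/10)`. Every read carries a truth record (fragment, position,
strand) consumed by the Oracle and all accuracy metrics.

What the parametric simulator does *not* capture: sequence-specific
sampling bias, PCR chimeras, GC effects, structural variants beyond the
planted duplications, and the empirical stencil shapes of any particular
library prep (an empirical-stencil mode that replays cloud shapes from a
user SAM is available). Passing accuracy numbers on these simulations
therefore demonstrates correctness of the inference given the generative
assumptions, not performance on any particular real library.

Paired-end mode in the simulator emits mates, but the alignment pipeline
treats mates as independent single-end fragments; proper concordant-pair
domains are future work and the well model is unchanged either way.

## Evaluation harness

Four comparators are computed per well: **Baseline** (pass-1 single-hit
alignments with weight-based MAPQ), **Naive** (best pass-2 hit on the
abbreviated reference, score-gap MAPQ, lifted to the genome; duplicate
same-locus hits from overlapping contigs are deduplicated before the gap
is computed), **RFA** (the full random-field pipeline), and **Oracle** (a
read is placed at its true position whenever the multi-hit aligner returned
it — the selector's upper bound). A placement is correct within ±5 bp on
the same strand, confident at MAPQ >= 10; reporting covers all reads and
the multimapped subset (more than one *distinct genome placement* among
pass-2 candidates — contig duplicates of one locus do not make a read
multimapped).

## Numerical and design choices

* Coordinates are 0-based half-open internally; 1-based only in SAM.
* Scott's-rule KDE bandwidths on `(log S, log lambda)`, floored at 0.05
  against degenerate training sets; marker states with under 20
  observations fall back to the pooled density; at most 256 support points
  per state are stored (deterministic thinning).
* `p_e` (seed-is-real prior) = expected true fragments per well
  (`well_fraction * G / mean(S)`) over candidate clouds per well, clamped
  to [0.05, 0.95].
* The assignment objective reported by `score_assignment()` is the sum of
  molecule log-potentials; the optimizer's full objective adds the
  off-target term for unassigned reads and is exposed as an attribute.
* Ties on equal move deltas keep the current assignment; all randomness is
  seeded from the configuration.
* Simulation-study problem sizes used throughout the tests and the
  acceptance script: a 5-Mb genome, 50 wells (~75k reads), chosen so the
  whole study exercises every pipeline stage at meaningful multimapping
  rates while remaining a desk-scale computation.

## Known limitations

* If pass 2 never produces the true candidate alignment (very high copy
  number, cap overflow), the read cannot be recovered; its quality is
  driven to 0 instead.
* Cross-well information sharing is deliberately absent: wells are
  independent by assumption, which forgoes some power at shared variants.
* The uniform location prior ships alone; the hook for protocol-specific
  location bias exists (`P(L | E)`) but has a single instantiation.
* Indels are penalised, not modelled in the hidden sequence; indel variant
  discovery is out of scope.
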
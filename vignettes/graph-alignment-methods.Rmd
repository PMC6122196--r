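---
title: "Aligning short reads to a de Bruijn graph: methods and design notes"
author: "dbgalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning short reads to a de Bruijn graph: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbgalign)
```

## The problem

A de Bruijn graph built from a reference genome at word length $k$ has
unitigs (maximal non-branching runs of $k$-mers) as nodes and $k{-}1$-base
overlaps as arcs. Every substring of the genome of length $\ge k$ spells a
walk through this graph, but the converse fails: once a walk spans three or
more nodes it may thread a combination of branches that occurs nowhere in the
genome. Aligning a short Illumina read (100–300 bp, roughly 1–2%
substitution errors) to the graph therefore poses two problems at once: a
search problem — among the up to $4^{l-k}$ walks reachable from a seed, find
the one most similar to the read — and a specificity problem — avoid walks
that exist in the graph but not in the genome. `dbgalign` addresses the first
with a best-first branch-and-bound search and the second with a two-pass,
higher-order Markov model over walks.

The graph is bidirected: one unitig sequence is stored per canonical
orientation (the lexicographic minimum of the sequence and its reverse
complement) and signed node identifiers select the strand, so
reverse-complement reads are first-class. $k$ is restricted to odd values so
that no $k$-mer is its own reverse complement. A consequence worth noting:
when the genome contains a sequence directly adjacent to its own reverse
complement (a hairpin fold), unitig compaction stops at the fold rather than
double-covering it; the affected substrings remain alignable through walks
across the fold arc.

## Seeding

Every $k$-mer of the read is looked up in a canonical $k$-mer hash index
(default $k = 31$); hits that are contiguous in both the read and one
oriented unitig are merged into maximal runs and tried longest-first. Because
the index is canonical and node identifiers are signed, a reverse-strand read
produces the mirrored seeds directly — a second alignment of the
reverse-complemented read would retrace exactly the mirrored search and is
therefore skipped.

Reads whose every $k$-mer is broken by an error fall back to maximal exact
matches (MEMs) between the read and the unitigs, necessarily shorter than
$k$. MEMs are found from a cached index of 15-mers (the default minimum MEM
length) extended maximally in both directions; a quadratic all-substring scan
serves as the test oracle for this component. The floor of 15 balances
sensitivity against spurious anchors on small genomes; it is configurable.

At most 10 seeds are tried per read (`seed_retry_cap`), and seed iteration
stops early once an alignment within `seed_stop_slack` (default 4) score
points of the perfect score is in hand — with the default scores that means
at most two substitutions, after which a longer-seeded anchor cannot be
beaten in practice. The per-seed search itself is exact; the cap and the
early stop only bound how many alternative anchors are explored.

## Branch-and-bound extension

From a seed ending in node $v$ with unaligned read remainder $s$ (length
$l$), the search explores chains starting at $v$. For a chain with spelled
sequence $w$, a dynamic-programming row holds the global alignment score
$f(w, s[1:n])$ of the full spelled sequence against every read prefix $n$
under match/mismatch/gap scores of $+1/-1/-3$ (linear gaps). The chain's
priority in the queue is $\max_n f(w, s[1:n])$ — the greedy heuristic of
extending the currently best-looking path first. A complete alignment is a
cell in which the entire remainder has been consumed by some prefix of the
spelled chain; the best such cell defines the reported walk, which is
trimmed to the node containing it.

Pruning uses an admissible bound. For an alignment that leaves the current
DP row at column $n$, no continuation can add more than a match per
remaining base, so its completed score is at most $f(w, s[1:n]) + m(l-n)$.
The bound attached to a queued state is the maximum of this quantity over
all $n$; a state whose bound falls below the best complete alignment found
so far is discarded. Note that taking the formula only at the maximizing
$n^\*$ would not be admissible under gap moves — an alignment crossing the
row at $n' < n^\*$ can exceed $f(w,s[1:n^\*]) + m(l-n^\*)$ by up to
$|g|\,(n^\* - n')$ — which is why the maximum over all columns is used; the
single-column form is still exposed as `upper_bound()` for the bound's
arithmetic itself. States whose bound *equals* the incumbent are still
expanded, so equal-scoring walks are compared under deterministic tie-breaks
(longer consumed prefix, then lexicographically smaller chain).

Two caps keep the search finite and fast without affecting results in
practice:

* **Horizon.** Chains stop growing once their spelled length reaches
  $l + 8$: every spelled base beyond the read end costs at least one gap, so
  an optimum using more than 8 surplus bases would require more than 8 net
  deletions in a short Illumina read. The same horizon defines the search
  universe for the pruned search, the unpruned search, and the enumeration
  oracle in the test suite, so the optimality tests compare like with like.
  Node tails are truncated to this horizon before entering the DP, which is
  what keeps extensions bordering megabase-scale unitigs cheap.
* **Budget.** A per-read budget of 10,000 queue pops bounds pathological
  repeat regions; a read that exhausts it keeps its best-so-far alignment
  and is flagged. The worst case of the underlying problem is exponential in
  $l - k$, so some cap is unavoidable.

Left extension reuses the same machinery by symmetry: the left remainder is
reverse complemented and extended from the mirrored seed node $-v$, with the
already-computed right chain supplying mirrored model context. The reported
score and identity are recomputed from the corrected sequence against the
read with a full Needleman–Wunsch pass, so `score` is always exactly the
similarity of what is reported, not an artifact of how the pieces were
assembled. A read is reported aligned when its identity (matches over
alignment columns) reaches `min_identity = 0.75`; unaligned reads are passed
through unchanged so the corrected output preserves cardinality and order.

## Implicit repeat resolution

Training (pass 1) aligns all reads without restrictions. Every aligned
read's walk, together with its reverse-complement mirror, contributes all
contiguous $(n{+}1)$-node subwalks for orders $n = 2,\dots,10$: the first
$n$ nodes are the state, the last is the continuation (head). Order 1 is
deliberately absent — every single arc is genuine by construction, so a
1-state model cannot discriminate.

Two error regimes are handled explicitly:

* **Spurious observations** (misaligned erroneous reads). Each observed
  (state, head) pair is tested with a Poisson likelihood ratio comparing a
  multiplicity-zero model ($\lambda = 1$) against a multiplicity-one model
  ($\lambda = C_M$): $\mathrm{LR} = e^{C_M - 1} C_M^{-freq}$, computed in
  log space. Transitions with $\mathrm{LR} \ge 10^5$ are pruned. With the
  default threshold this only ever fires when $C_M \gtrsim 13.7$, so
  singleton observations in well-covered contexts are removed while sparse
  contexts are left untouched. A state whose every observed continuation was
  pruned is retained: such a state arose purely from misalignment, and it
  rejects any candidate continuation (subject to the usability gate below).
* **Missing observations** (coverage gaps). The expected number of reads
  covering a path whose spelled sequence has length $M$, at coverage $c$ and
  read length $l$, is $C_M = c\,(l - M + 1)/l$, with $C_1 = c$ and $C_M = 0$
  beyond $M = l$; the implementation also satisfies the recurrence
  $C_M = C_{M-1}(l - M + 1)/(l - M + 2)$, which the tests check directly. A
  state is only consulted when the queried (state + head) path reaches
  $C_M \ge$ `min_chain_cov` $= 10$; below that, absence of evidence is not
  treated as evidence of absence.

$M$ is the full overlap-collapsed spelled length of the $(n{+}1)$-node walk.
This has a visible consequence: any context that includes a long flanking
unitig is never usable, because no read can contain its sequence. Branch
choices made immediately at the boundary of a long unique region therefore
remain outside the model's reach by design; the model earns its keep in
repeat interiors where nodes are short.

At alignment time (pass 2) a candidate extension is validated by examining
orders from the highest available down to 2: the first usable, observed
state decides; if none exists the extension is allowed. Higher order wins
because it carries strictly more context — the canonical example being a
3-state table resolving a branch that the 2-state table must leave open.
Coverage $c$ is estimated from pass 1 (aligned bases over total graph
length) and $l$ is the modal read length, so training is self-contained.
Pass 2 realigns only reads whose first-pass walk spans at least three nodes:
shorter walks cannot be restricted by any order $\ge 2$, so their
unrestricted optimum is already final. Each read's best alignment alone
contributes observations; probabilities over surviving heads are stored for
inspection but only presence/absence drives validation.

## The read simulator and what the tests do (and do not) show

The simulator emulates ART-style Illumina simulation in its statistical
skeleton: fixed-length reads sampled uniformly from both strands, uniform
per-base substitutions at a configurable rate (default 1%), optional indels,
and an error-free twin per read recorded in matching order. Position-
dependent quality profiles, GC bias and paired-end structure are not
modelled; qualities are written as constant Q40 and the aligner is
quality-blind throughout. Passing tests therefore demonstrate correctness of
the graph, search and model machinery under idealized error structure — they
do not certify accuracy numbers on platform-specific real data.

The planted-repeat generator produces an i.i.d. background with
non-overlapping copies of one repeat, each copy independently mutated at a
small divergence in `near-identical` mode. Synthetic study conditions used
by the acceptance checks:

* **Clean genome**: 20 kb, no repeats, 150 bp reads at 25×; error-free
  reads must be 100% correctly aligned (the graph is complete and
  error-free, so the true walk always exists), and 1% substitutions must
  stay at or above 99% over ten replicates.
* **Repeat genome**: 50 kb with four copies of a 300 bp repeat at 0.8%
  divergence, 300 bp reads at 30× with 2% substitutions. These values
  follow from the model's own usability bound rather than taste: a state is
  usable only if $M \le l\,(1 - \mathrm{minChainCov}/c) + 1$, i.e. 201 bases
  at $l = 300, c = 30$. A divergence of 0.8% per copy across four copies
  puts the union of variant sites ~1/31 bp apart, which maximizes the number
  of shared anchor unitigs (an anchor needs an inter-site gap exceeding
  $k = 31$) while keeping arm-anchor-arm contexts under the usable bound.
  With *exact* repeat copies longer than the read length, by contrast, no
  read can ever walk a three-node path across the repeat, so the model
  provably cannot act at all — near-identical copies are the regime in which
  implicit repeat resolution is observable at desk scale. Read length and
  coverage sit at the MiSeq end of the platform range for the same reason.
  The acceptance check asserts that guided accuracy on multi-node reads is
  never below unguided accuracy in any of ten replicates and strictly better
  in aggregate.

## Numerical and degenerate-input choices

* Scores are integers throughout; the DP works in plain `int` with a
  sentinel far from overflow.
* The likelihood ratio is computed in log space; the tests pin it to the
  direct Poisson pmf ratio at $10^{-9}$ relative tolerance.
* Ties: seeds of equal length by smaller read offset then smaller node id;
  queue pops by longer consumed prefix then lexicographically smaller chain;
  equal-scoring strands resolve to the seeded orientation. Reruns are
  byte-identical, and the output contract (order = input order) is
  independent of the configured worker count.
* Degenerate inputs: non-ACGT characters split references into fragments;
  reads shorter than $k$ go straight to the MEM fallback; an empty remainder
  extends to the seed node alone; a read with no anchor at all is returned
  unaligned and unchanged; training with zero aligned reads yields an empty
  model that restricts nothing (with a warning).
* Full (unbanded) DP rows are used rather than a banded approximation:
  remainders are at most a read long, the horizon bounds the other
  dimension, and the C++ kernel makes the full row cheaper than the
  bookkeeping a safe adaptive band would need.

## Known limitations

* Repeats longer than the read length with exact copies are out of reach of
  the model by construction (nothing observable distinguishes the copies);
  this is a property of the method, not of the implementation.
* Branch decisions adjacent to long unique unitigs are unprotected because
  their context paths exceed any read length (see the $M$ discussion above).
* The gap model is linear; affine gaps would change both the DP and the
  admissible bound.
* Paired-end information is ignored; pairs are treated as independent
  reads.
* The per-read budget means adversarially repetitive graphs can return a
  flagged best-so-far alignment rather than the exact optimum.
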
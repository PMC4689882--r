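---
title: "Dominant-keyword prediction for PPI extraction: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominant-keyword prediction for PPI extraction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dkppi)
```

## The problem

Protein–protein interaction (PPI) extraction treats every pair of protein
mentions in a sentence as a binary classification *instance*: does the
sentence assert an interaction between the two? Supervised extractors
represent each instance by features of the sentence and train a classifier
on gold-annotated corpora.

One lexical feature — the interaction *keyword* ("bind", "interact",
"regulate", …) nearest the pair — often dominates that decision. When it
does, it is superb evidence; when it does not (the keyword belongs to a
different clause, or to a different pair), leaning on it drowns out the
features that actually matter. Whether a keyword is *dominant* is a
property of the instance, not of the word: the same "bind" can decide one
sentence and be a bystander in the next. `dkppi` implements a pipeline
that predicts, per instance, whether its keyword is dominant (the *DK
value*), partitions the training set by that prediction and by the
keyword's position, and trains one classifier per cell.

## The feature encoding

Every instance is encoded in exactly 44 dimensions, computed on tokens in
which the pair is blinded to `PROT1`/`PROT2` and other proteins to `PROT`:

* **25 lexical features**: the selected keyword stem; three word
  distances (P1–K, P2–K, P1–P2, counting word tokens strictly between the
  anchors, with the pair's own protein tokens not counted — the keyword
  does count, which is what makes the infix identity
  `type1 + type2 + 1 = type3` hold); the keyword position expanded to three indicators
  (infix = P1–K–P2, prefix = K–P1–P2, postfix = P1–P2–K); the two 1-based
  protein positions; the comma configuration over the two anchor gaps;
  negation and condition flags scoped *between* the anchors; conjunction,
  "which" and "but" flags scoped over the whole sentence; the preposition
  following the keyword within a word distance of 3; a multiple-keyword
  flag; seven *second keyword* flags (bind, interact, regulate, induce,
  stimulate, associate, known — fired only when the word occurs between
  the proteins and is not itself the selected keyword); and a
  parallel-expression flag (pair separated only by `— / and or (`).
* **6 parse features**: for P1, P2 and K, the height and the
  part-of-speech path from the root of a bracketed constituent tree,
  excluding the root label and including the preterminal. The convention
  is fixed by the worked example "P1 is driven by P2", whose heights are
  (2, 5, 3) with paths `NP,NN` / `VP,VP,PP,NP,NN` / `VP,VP,VBN`.
* **13 pattern features**: surface patterns over the blinded stems
  (`P1 * iVerb * P2`, `iNoun between * P1 * and * P2`,
  `between P1 and P2`, …) where each wildcard `*` absorbs 0–5 word
  tokens and `iVerb`/`iNoun` are interaction verb/noun stem sets.

This expansion — position as three indicators, everything else one
dimension — is the only convention under which the registry totals 44
(25 + 6 + 13), and `ppi_feature_names()` is the single source of truth
for it.

All lexicon membership is tested on Porter stems, computed by the
package's own tested implementation of the classic five-step algorithm;
the shipped lexicon file stores raw words and is stemmed at load time so
that both sides of every comparison pass through the same normalisation.

## Dominant-keyword refinement

For a keyword $K$, the *unbalance degree*

$$U(K) = \frac{\#\,\text{positive instances whose selected keyword is } K}
              {\#\,\text{instances whose selected keyword is } K}$$

measures class bias: $U = 0.5$ is perfectly balanced, $U \in \{0, 1\}$
perfectly unbalanced. Initially, an instance receives $DK = 1$ exactly
when $\min(U, 1-U) < T$ for its keyword (strictly — the boundary case
$\min(U,1-U)=T$ is not dominant), with $T = 0.15$ by default.
"Containing $K$" is read as *selected keyword equals $K$*, since the
initial assumption partitions instances by their keyword feature value.

The assumption is then refined by $m$ rounds of $k$-fold
cross-validation. In each round the surviving instances are partitioned
into label-stratified folds; for each fold, two classifiers are trained
on the complement — $C_0$ on the $DK=0$ side, $C_1$ on the $DK=1$ side,
each on all 44 features — and each fold instance is updated:

1. **Predictions differ**: the side whose classifier is correct wins
   ($DK \leftarrow 1$ if only $C_1$ is right, $0$ if only $C_0$ is).
2. **Both correct**: a true-negative instance has its $DK$ flipped with
   mutation probability $\alpha$, an escape hatch from local stable
   states. Positives are left alone because they are scarce.
3. **Both wrong**: a gold-negative instance is removed from the training
   set; positives are never removed.

Defaults $k = 10$, $m = 5$, $\alpha = 0.05$ are the method's reference
conditions. Design points that the procedure leaves
open were fixed as follows: removals take effect immediately (subsequent
folds in the same round no longer train on them); the fold partition is
redrawn every round (`repartition = FALSE` reuses the first draw);
mutation draws come from a dedicated seeded stream so that setting
$\alpha = 0$ does not shift the fold randomness; and a training side that
is empty or single-class degrades to a majority-label stub rather than
failing.

A *DK-classifier* is then trained on the survivors with $DK$ as the class
label, and assigns $DK$ values to unlabeled instances at prediction time.

## Partition and the five method variants

Survivors are partitioned by $DK$ × keyword position: II ($DK=1$, infix),
IP ($DK=1$, prefix/postfix), NI ($DK=0$, infix), NP (everything else —
including keyword-less instances, a fallback this package fixes
explicitly). Manual feature selection removes four pattern features per
cell: the infix cells drop the phrase patterns (7, 8, 9, 13), the
prefix/postfix cells drop the S-V-O patterns (1, 2, 10, 12).

The five variants compose these pieces: **SC** (one classifier, no
partition), **MC** (partition with $DK$ taken directly from the unbalance
degree; at prediction time an instance is routed by whether its keyword
stem is in the training-derived dominant set), **DK-MC** (adds refinement
and the DK-classifier), **FS-MC** and **DK-FS-MC** (add the masks).
The base learner is a random forest (`ranger`), run single-threaded with
a fixed seed. The default is 100 trees: on corpora of a few hundred
instances and 44 features, accuracy is flat well below that, and the
refinement loop fits on the order of a hundred forests per outer fold, so
the default favours the smallest forest past the plateau; `num_trees` in
`ppi_config()` raises it where a larger corpus warrants. The per-split
feature sample is a third of the features rather than the conventional
`sqrt(p)`: decisive evidence here is sparse (a negation flag, a comma
configuration, one keyword level), and at `mtry = 6` of 44 the trees
often fail to draw it, which both weakens every classifier and — more
subtly — biases the refinement: Case 1 interprets any out-of-fold error
of one classifier as evidence about dominance, so avoidable base-learner
variance converts directly into spurious DK flips.

Evaluation pools confusion counts over stratified outer folds (micro
average) — the refinement runs entirely inside each training side — and
per-fold and macro values are reported alongside. Folds are stratified at
instance level; document-level splitting is a known stricter alternative
for corpora with many near-duplicate pairs and is out of scope here.

## The synthetic generator

Real benchmark corpora require external downloads and a specific parser,
so the package ships a generator (`synth_generate()`) that emulates the
*statistical* structure the method assumes, not biomedical fluency:

* Sentences instantiate hand-written template families for the three
  keyword positions (S-V-O for infix, "interaction of A with B"-style for
  prefix, "A and B interact"-style for postfix), each with a fixed
  bracketed parse tree whose leaves are exactly the word tokens.
* Two designated keywords are dominant, one on each side of the class
  balance, mirroring the two "completely unbalanced" poles of the
  unbalance degree: instances drawing "interact"/"interaction" are
  positive with probability `dominance`, instances drawing
  "colocalize"/"colocalization" are positive with the mirrored
  probability `positive_rate·(1 − dominance)/(1 − positive_rate)`; both
  carry `planted_dk = 1`. At `dominance = 1` their unbalance degrees are
  exactly 1 and 0; at `dominance = positive_rate` both collapse into the
  background and no keyword is dominant. All other instances are
  context-driven (`planted_dk = 0`) with `Bernoulli(positive_rate)`
  labels; context negatives carry a visible class cue — a negation word
  or a comma between the anchors — while dominant-keyword instances
  never do (there the keyword itself is the evidence). The cues are deliberately ones the 44-feature
  encoding can see (the negation flag and the comma feature): the
  refinement loop can only attribute an instance to the non-dominant side
  if the context evidence is visible to $C_0$, so a generator whose
  context classes were undetectable would make the planted ground truth
  unrecoverable by construction, for any method.
* Optionally (`extra_mention_rate`) sentences carry a third mention
  whose extra pairs are negative with `planted_dk = 0` — instances that
  *contain* the dominant keyword without being governed by it, the very
  case the per-instance DK notion exists for. Because such pairs dilute
  the dominant keyword's unbalance degree below its nominal `dominance`
  level (and can push it across the `T` threshold), the default leaves
  them off; tests enable them explicitly when stressing enumeration and
  keyword ambiguity.
* Position mix 0.6/0.2/0.2; `positive_rate` 0.3; 25% of keyword-bearing
  sentences use the positively dominant keyword and 15% the negatively
  dominant one; 5% of sentences have no keyword at all. The resulting
  corpora are negative-biased overall (roughly 43% positive at the
  defaults), matching the class imbalance of real PPI corpora.

What passing tests on this generator shows: the mechanics of the
pipeline — feature extraction, unbalance accounting, the three update
cases, routing, masking — behave as specified, and planted dominance is
recovered under the default study conditions. What it does not show:
performance on real biomedical prose, whose keyword ambiguity, parse
errors and annotation noise the templates do not model.

## Numerical conventions and degenerate inputs

* Character offsets are 0-based half-open internally; the XML interchange
  format's inclusive `charOffset` ranges are converted on the way in and
  out. Token indices are 0-based; the position features are 1-based.
* Multi-word mentions collapse to a single word token (so distances match
  single-word worked examples); in parse trees they absorb their leaves
  and take the last (head) leaf's path.
* Keyword selection minimises the summed distance to the pair; ties go to
  the leftmost candidate. Sentinels: −1 for undefined distances and
  heights, `"none"` for undefined nominals, `FALSE` for undefined flags.
* Wildcards match 0–5 words — zero included, otherwise the three-word
  S-V-O archetype could not match its own pattern.
* Recall/precision/F return 0 with a `degenerate` flag on zero
  denominators; counts are validated non-negative.
* Missing or unalignable parse trees degrade the six parse features to
  sentinels instead of erroring, so tree-less corpora still run.

## Problem sizes used by the shipped tests

The test suite exercises the full refinement at n = 500 sentences
(dominance 1.0) for parameter recovery and n = 600 (dominance 0.9,
five seeds) for the SC vs DK-FS-MC comparison; module tests use corpora
of 30–120 sentences with reduced fold/iteration counts. These sizes are
the package's chosen desk-scale reference conditions; all of them are
regenerated from seeds at test time.

## Known limitations

* There is no canonical keyword list for this task; the shipped lexicon
  is a curated 180-stem list and is configurable (`read_lexicon()`), so
  absolute scores on real corpora will depend on the lexicon supplied.
* No constituent parser is bundled; trees are an input (an adapter can be
  wired through `read_parse_trees()`-compatible files).
* Instance-level cross-validation is the default; document-level
  splitting, class-weighted forests, and data-driven feature selection
  are out of scope.
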
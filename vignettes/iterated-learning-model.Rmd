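---
title: "The iterated-learning model behind combilearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The iterated-learning model behind combilearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combilearn)
```

combilearn simulates how combinatorial signal structure — the reuse of a
small set of meaningless elements across a lexicon, the lower half of
duality of patterning — can emerge purely from cultural transmission among
Bayesian learners. This vignette is the package's own account of the
model: its assumptions, its tunable parameters, the design choices that
were genuinely open, and what the simulations can and cannot show.

## The hypothesis space of languages

A *language* is a total mapping from 4 atomic meanings to signals drawn
from a fixed inventory of 8 two-character tokens:

```{r}
signal_inventory()
```

The first and second characters model two abstract phonological slots
(e.g. location and handshape in a sign, or onset and rhyme in a
syllable). The inventory splits into two blocks — `a, b` only combine
with `c, d`, and `p, q` only with `r, s` — so full recombination of parts
is possible but not forced. Signals may be shared across meanings, giving
$8^4 = 4096$ languages. Each is classified:

* **degenerate** — one signal for all meanings (8 languages),
* **holistic** — four distinct signals without full recombination of
  parts (1632),
* **combinatorial** — four distinct signals forming the complete
  Cartesian product of two values per position, i.e. a lexicon of minimal
  pairs (48),
* **other** — everything else, e.g. partially degenerate mappings (2408).

```{r}
space <- enumerate_languages()
class_counts(space)
```

A design note on the **holistic predicate**. Two readings of "holistic"
are possible: (i) distinct signals with *no reuse of any character* and
(ii) distinct signals that simply fail to be fully combinatorial. Reading
(i) admits only 96 languages; reading (ii) admits 1632 and is the one
this package uses, because it makes the four classes an exhaustive
partition with the census above. A consequence worth knowing: under
reading (ii) holistic languages do not share a single coding length (see
below) — they range up to 24 bits, with the maximum attained exactly by
the 96 character-disjoint lexicons such as `ac bd pr qs`.

## The simplicity prior

Learning bias is modelled as a preference for compressible languages.
Writing a language as its concatenated 8-character string, each character
occurrence is coded with its within-language relative frequency
$p(l_i)$, giving the description length

$$L(l) = -\sum_i \log_2 p(l_i),$$

and the prior $P(l) \propto 2^{-L(l)}$. Degenerate languages cost 8 bits,
combinatorial ones 16, and the character-disjoint holistic ones 24, so a
degenerate language is $2^{16}$ times more probable a priori than a
canonical holistic one. The character frequencies are computed per
language, not from any corpus: that is the only reading under which the
three reference lexicons come out at 8/16/24 bits.

```{r}
inv <- signal_inventory()
c(degenerate    = coding_length(c("ac", "ac", "ac", "ac"), inv),
  combinatorial = coding_length(c("ac", "ad", "bc", "bd"), inv),
  holistic      = coding_length(c("ac", "bd", "pr", "qs"), inv))
```

## Learning

Each agent carries a full posterior over all 4096 languages — the space
is small enough that no approximate inference is needed. On observing a
meaning–signal pair $(m, s)$ the posterior is updated by Bayes' rule with
the likelihood

$$P(s \mid l, m) \propto \begin{cases} 1 - \epsilon & \text{if } l \text{ pairs } m \text{ with } s \\ \epsilon / 3 & \text{otherwise,} \end{cases}$$

with $\epsilon = 0.05$ by default. The off-diagonal denominator 3 is kept
as a fixed constant of the model (the error mass is spread as if over the
three signals "for the other meanings") even though the inventory holds 7
non-target signals; the production-noise model below *does* use all 7
alternatives. The two are deliberately not reconciled — the likelihood is
a learner's simplifying assumption, not a description of the true
production channel — and the `n_wrong` argument lets users explore the
alternative. Updates are sequential and order-independent, so agents need
not store data; they are carried out in linear double precision, which is
safe because one update rescales 4096 well-scaled weights (the smallest
possible factor, $\epsilon/3 \approx 0.017$, cannot underflow).

## Production

Speakers are communicatively rational in a simplified, single-level way
(no recursive reasoning about listeners). For meaning $m$ the speaker
scores every signal by

$$\mathrm{score}(s) = \sum_l P(l \mid d) \, C(s \mid l, m), \qquad
C(s \mid l, m) = \begin{cases} (1/a)^{\gamma} & \text{if } l \text{ pairs } m \text{ with } s \\ 0 & \text{otherwise,} \end{cases}$$

where $a$ is the *ambiguity* of $s$ in $l$ — how many meanings $s$ covers
— and $\gamma \ge 0$ is the communicative-rationality exponent. With
$\gamma = 0$ the speaker only cares that the signal can mean $m$; with
$\gamma = 100$ (the default "high pressure" setting) ambiguous signals
are effectively vetoed, since even $a = 2$ is penalised by $2^{-100}$.
The speaker emits the argmax of the scores, then with probability
$\epsilon$ replaces it by one of the 7 other signals uniformly at random
(production noise).

Numerical choices: scores are computed in plain double precision —
$(1/4)^{100} \approx 6 \times 10^{-61}$ is comfortably representable, so
no log-space machinery is used. Argmax ties are broken uniformly at
random rather than by index; in symmetric states (a newborn agent, whose
prior is invariant under relabelling of the two blocks) an index-ordered
tie-break would systematically favour low-index signals.

## Population turnover and the two transmission conditions

A population of 10 agents is initialised committed (point-mass posterior)
to the holistic language `ac bd pr qs` — maximally distant from a
combinatorial system while communicatively optimal. The point mass is the
limiting case of an agent trained on unlimited data from that language.
Each iteration:

1. the oldest agent dies and an untrained newborn (posterior = prior)
   joins, so ages always form $\{0, \dots, 9\}$;
2. 20 communication episodes take place: a uniform random meaning, a
   producer fixed by the condition, and a uniformly chosen *other* agent
   who updates its posterior on the emitted pair;
3. the oldest agent's posterior, aggregated into the four class masses,
   is recorded (end of iteration, after the episodes).

The two conditions differ only in the producer:

* **oldest** — vertical transmission: the most experienced agent (age 9)
  always produces, as in a village sign language where children learn
  from elders;
* **midlife** — horizontal transmission: the producer is the agent of
  age 5, still learning, as in a deaf-community school setting. Age 5 is
  the unique "half-way" choice under which a focal agent's nine lifetime
  producers split five older / four younger
  (`lifetime_producers("midlife")` enumerates this analytically).

Ten iterations replace the whole population, so 2000 iterations are 200
generations. Within an iteration the same learner may be drawn more than
once; learner draws are independent.

## What a run produces, and the batch layer

`run_simulation()` returns a per-iteration trace of the oldest agent's
class masses; `run_batch()` repeats it with per-run seeds drawn without
replacement from a base-seed stream (distinct runs are guaranteed
distinct streams, and each run is reproducible in isolation). The
*crossover generation* of a run is the first generation at whose final
iteration the combinatorial mass exceeds the holistic mass; batches are
summarised by the median over runs, with never-crossing runs entering
the median as $+\infty$ so they cannot drag it downward. Crossover is
evaluated per run and then summarised, never on the mean trace, because
"overtaking in the majority of runs" is a statement about runs, not
about the average trajectory.

```{r, eval = FALSE}
cfg <- simulation_config(n_iterations = 200, gamma = 100,
                         condition = "midlife")
batch <- run_batch(cfg, n_runs = 50, base_seed = 2026)
summarize_crossovers(batch)
plot_panels(list(batch), file = "midlife.png")
```

## Expected dynamics, and how the tests pin them down

Three regimes structure the parameter space, and the package's test
suite asserts each at scaled-down batch sizes chosen to keep a full test
run at desk scale (50 runs of 200 iterations for the fast condition, 20
runs of 2000 iterations for each slow one; the published qualitative
picture is already stable at these sizes):

* $\gamma = 0$, oldest producer: with no pressure against ambiguity,
  iterated learning converges toward the prior, and the maximally simple
  degenerate languages dominate the oldest agent's posterior by the end
  of 200 generations.
* $\gamma = 100$, oldest producer: degenerate languages are unstable
  (producers avoid their ambiguous signal), and the combinatorial
  languages — the simplest unambiguous ones, hence the optimal
  learnability/expressivity trade-off — dominate eventually.
* $\gamma = 100$, midlife producer: the same end state arrives roughly
  an order of magnitude faster, with the median run crossing over by
  generation 4. Young producers' output is closer to their prior, so the
  simplicity bias is injected into the data stream every generation
  rather than filtered out by a lifetime of learning. The test suite
  hard-asserts a conservative acceleration ratio of at least 3 between
  the two conditions' median crossover generations (sampling noise at 20
  runs makes the observed ratio, which it also reports, fluctuate) and a
  median crossover generation of at most 4 in the midlife condition.

## What the model does not capture

The simulator is deliberately minimal. Its signals have two slots and
two usable values per slot; there is no compositionality (meanings are
atomic), no network structure beyond the single producer rule, no
variable lifespans, no listener-side pragmatics, and no
probability-matching (production is strict argmax plus noise). Passing
tests therefore show that the learnability/expressivity trade-off and
the learning-from-learners acceleration hold in this minimal setting —
they do not quantify either effect for any real emerging sign language,
where lexicon sizes, interaction networks and iconicity all matter.
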
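---
title: "An executable kernel for dynamic decision-making: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An executable kernel for dynamic decision-making: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dominoagent)
```

## The model

`dominoagent` implements the decision lifecycle of a cognitive agent as
ten typed operations — the columns of the domino architecture in which
beliefs lead to goals, goals to candidate solutions, candidates to
commitments, and commitments back to new beliefs, plans and actions. Each
operation is a contract over cognitive-state types (belief, goal,
candidate, reason, merit, commitment, plan, expectation), and the kernel
sequences them in a fixed cycle:

perceive → S1 (belief maintenance to the derivation fixpoint) → S9
(expectation monitoring) → S2 (goal raising) → S3–S6 (the decision
pipeline on the highest-priority pending decision goal) → S7/S8 (plan
enactment and action) → S10 (learning, when a decision process has
terminated).

The architecture itself fixes no algorithm for any operation; this package
commits to one concrete, deterministic instantiation per operation and
documents every such commitment below. All randomness (tie-breaks, deck
shuffles, retention draws) flows from a single integer seed, so a run is
a pure function of (knowledge base, scenario, seed) and traces replay
bit-identically.

## The knowledge level

Background knowledge is an ontology: a concept network with
*is-a-kind-of* links, property assertions, inter-concept relations from a
declared vocabulary, rules, goal templates, argument schemas, plan
templates, and scenario/task models. The formalism is deliberately the
minimum needed to encode the package's two scenarios — frames with
multiple inheritance, not a description logic; there is no satisfiability
or classification reasoning, and no external terminology import.

Choices that were genuinely open:

* **Multiple inheritance.** The is-a graph is a DAG, not a tree; ancestor
  traversal is breadth-first and deduplicated. `is_a()` is the
  reflexive–transitive closure of the parent links.
* **Property shadowing.** A property declared on a descendant overrides a
  same-named ancestor property (specific-over-general, the standard
  convention in frame systems); among equally specific ancestors the first
  in breadth-first order wins, making lookup deterministic.
* **World assumption.** Descriptions evaluate three-valued (true / false /
  unknown) with strong Kleene connectives. The default is open-world: an
  atom absent from the belief set is *unknown*. Goal conditions and rule
  antecedents that need negation-as-failure opt in per rule
  (`closed_world: true`); goal termination always evaluates closed-world,
  since a goal is a description that does not *currently* hold and is
  achieved exactly when it becomes true.
* **Variables and matching.** Rule patterns write variables as `?name`;
  matching is plain conjunctive unification against the ground belief
  atoms (beliefs are ground, so no occurs-check is needed). Antecedents
  with variables must be conjunctions of literals; arbitrary ground
  formulas are evaluated directly.

## Working memory and reason maintenance

Every cognitive state is a working-memory item tagged with one or more
justifications naming its grounds: observation, inference (with the rule
and the supporting item ids), commitment, communication, assumption, or
axiom. Retraction cascades: an item survives only while at least one of
its justifications has all supports active, so the active set is always
the least fixpoint of derivation from the ground items
(`wm_wellfounded()` recomputes that fixpoint from scratch and the test
suite holds the two equal after arbitrary assert/retract sequences).

Consistency policy (the model requires a consistent belief state but does
not dictate how to restore it): on asserting an atom that contradicts an
active belief, observation-backed items outrank inference-backed ones, and
between two observations the most recent wins; the loser is retracted with
cascade. A firm commitment whose supports are later retracted is *flagged
for re-decision*, not auto-retracted — reconsideration is triggered, but
an irreversible commitment is not silently undone.

Item ids are monotonically increasing integers per agent and cycle stamps
come from the kernel clock, which is what makes traces replayable.

## Argumentation and aggregation

Reasons are instantiated from declarative schemas: *pro* and *con*
schemas target a candidate, *undercut* schemas target the arguments of a
named schema. Schema applicability conditions cover the cases the
scenarios need — the candidate's (inherited) properties, a relation of the
candidate whose object is believed to be in a given state (the
treatment-exacerbates-condition pattern), or a ground belief — plus an R
function escape hatch through which scenario code registers bespoke
reasons such as card feature matches.

* **Defeat semantics.** Grounded (skeptical) labelling of the undercut
  graph: an argument is defeated iff attacked by an undefeated
  undercutter; labels are propagated iteratively to fixpoint. Members of
  undercut cycles stay undecided and are *not* treated as defeated. The
  grounded choice is the weakest semantics that already decides the
  canonical three-reason example (R1 pro A, R2 pro B, R3 undercutting R1
  — prefer B), and the test suite checks it against exhaustive
  minimal-complete-extension enumeration on graphs of up to 12 arguments.
* **Rebuttal is not defeat.** Opposite-polarity arguments on the same
  candidate both count; they meet in the arithmetic, not in the attack
  graph. This is what makes the sum-of-reasons rule meaningful.
* **Aggregation.** The default aggregator is the Bentham rule: merit =
  Σ strength(undefeated pros) − Σ strength(undefeated cons). Schema
  strengths default to 1 and are configurable per schema. An `ordinal`
  aggregator (count undefeated pros minus cons, ignoring strengths)
  implements the purely logical variant in which defeat alone can decide
  the preference, and `register_aggregator()` accepts further rules
  (probabilistic or expected-utility instantiations are deliberately out
  of scope; only the interface is provided). A learned-frequency bonus
  can be mixed in (below).
* **Preference.** Candidates are ordered by descending merit; ties break
  by seeded random draw (default — with no discriminating reasons the
  choice is arbitrary), lexicographically, or by declared priority; a
  `"none"` policy records an impasse instead. The order is always total
  and consistent with the merits.

## Commitment

A decision goal commits to the top-ranked candidate. The commitment is
**firm** when (a) the top merit strictly exceeds the runner-up, (b) no
declared consultation source remains unexploited, and (c) the goal's
stakes are routine *or* the declared consultation for a high-stakes goal
has been carried out; otherwise it is **provisional**, and if a
consultation source is declared an information-seeking goal is raised.
The information-value condition behind firmness ("no further information
would change the preference") has no cost model here; the stakes flag
plus the consult-before-firm rule is an explicit operational stand-in,
chosen because it reproduces the clinical scenario's behaviour —
provisional aspirin, consult, firm clopidogrel — without inventing
numeric information costs. Accept-mode commitments assert the accepted
belief (whether a belief is acceptable is independent of the agent's
goals); adopt-mode commitments instantiate the serving plan template and
never outlive their goal.

## Plans, actions, monitoring, learning

Plans are task networks — enquiries, decisions, actions, sub-plans — with
completion-dependency arrows and logical preconditions; a task is enabled
when its predecessors are done and its precondition holds (the SOAP
pattern, two order-free enquiries before an assessment, is the shipped
example). Actions are atomic; on an unsatisfied precondition they are
postponed and requeued, and discarded after three retries (configurable).
Communication acts enqueue performative messages on the switchboard.

Monitoring matches observations against active expectations: a match
closes the expectation, a mismatch asserts an expectation-violation belief
justified by both sides. Learning, on decision termination, (1) appends an
episodic scenario model recording the goal and the beliefs held at
commitment and (2) increments a (context, decision) frequency counter that
aggregation can use as a weighting argument when `use_frequency` is set.

## The multi-agent layer

Agents share an ontology and carry disjoint specialist partitions; a
switchboard delivers messages FIFO, exactly once, with per-dialog
strictly-increasing sequence numbers. Dialog plans are realized as an
explicit protocol machine over the performatives inform, request, query,
explain, instruct, challenge, accept, reject: a consultation opens with a
request-to-open (accepted by the peer), proceeds with a request to confirm
the initiator's preferred option, and the responder runs its *own* full
decision pipeline — querying the records agent for case facts first —
before informing the initiator of its preference. The initiator challenges
advice exactly when it conflicts with its own current preference (the
simplest trigger that reproduces the scenario); the responder explains
with its undefeated argument set; the initiator asserts the communicated
arguments (deduplicating lines of reasoning it already constructed
itself), re-resolves defeat and re-aggregates. Re-aggregation rather than
a full re-decision is the implemented reading of the reconsideration step;
the test suite proves the two equivalent on this fixture by recomputing
the merits from scratch over the merged argument set. Agent turn order
within a round is registration order — a fixed serialization of what a
production system would do concurrently, without changing the quiescent
outcome.

### The clinical fixture

The shipped knowledge base encodes only the facts of the walkthrough: two
drugs known to the lead agent, three to the specialist; analgesic,
anti-clotting, availability and modest-price properties; the
exacerbation schema; and the assertion that aspirin exacerbates
gastritis, known only to the specialist. One calibration was required:
with all schema strengths at 1 the safety argument would exactly cancel
aspirin's price advantage and the specialist's preference would be a tie.
Strengths are explicitly configurable, and the fixture sets the
exacerbation con to strength 2 — a safety argument outweighs a
modest-price argument — making the stated preference order strict. This
is the package's own calibration of the fixture; the source scenario
states direction, not magnitudes.

## The card-sorting scenario

The deck is the standard 64-card set (every number × shape × colour
combination once), shuffled per 64-block; targets are one red triangle,
two green stars, three yellow crosses, four blue circles, so every
sorting rule picks a unique target for any card. The experimenter's
criterion rotates colour → form → number, switching without warning after
`switch_after = 6` consecutive correct placements (a configurable default;
the scenario literature says only "a series").

Two strategies:

* **Location (simplistic):** the four placements are the options; feature
  matches are the reasons; no cross-trial learning (learning enters only
  with the sophisticated strategy, so the simplistic one stays memoryless
  by design).
* **Rule (sophisticated):** the three sorting rules are the options. On
  positive feedback the rules matching the chosen target gain +1 argument
  strength and non-matching live rules are eliminated; on negative
  feedback while still searching, the rules consistent with the wrong
  placement are eliminated. Once a single rule is maintained, placement is
  routine, an expectation of positive feedback is asserted each trial, and
  only an expectation violation (monitoring) can dislodge the rule —
  feedback magnitudes are the package's choice (the account specifies
  direction, "stronger/weaker", not numbers; eliminating a disconfirmed
  rule is the limiting case of weakening).

Lesion toggles: `monitoring = FALSE` removes the violation pathway, so a
maintained rule persists against sustained negative feedback
(perseveration); `retention_failure = p` deletes the maintained rule
belief with per-trial probability *p* (set loss). Retention draws are
taken *before* the deck shuffle, so toggling monitoring never changes the
card sequence or the forget events within a seed — lesion comparisons are
paired.

Error scoring: a *perseverative* error occurs after at least one switch
and matches the immediately previous criterion; a *set-loss* error
follows at least three consecutive correct placements (common scoring
practice; a configurable threshold) with no intervening switch, **made
while a single rule was being maintained**. The qualifier is deliberate:
runs of coincidentally correct placements during rule search, ended by a
search error, would otherwise mimic set loss behaviourally (about one
event per twenty 128-trial runs), yet losing a set presupposes having
acquired one — the trial trace records the maintained-rule state, so the
classifier uses it. Perseverative takes precedence; the categories are
disjoint.

`wcst_reached_criterion()` checks that a run never gets stuck: a switch
happens exactly when criterion is reached, so every inter-switch segment
ends at criterion by construction and only the final segment is checked,
with a 25-trial allowance when the deck ends mid-segment (an intact agent
needs at most a handful of trials to re-identify the rule; 25 is a
generous bound, not a fitted one).

## Synthetic fixtures and what the tests do and do not show

`generate_random_fixture()` builds constructively valid random concept
DAGs (parents drawn among earlier concepts), relation tables, ground
belief sets, and small rule bases over a four-attribute alphabet. The
property suites run the implementation against independent brute-force
oracles — exhaustive path enumeration for inheritance, truth-table
enumeration for three-valued evaluation, substitute-and-test enumeration
for rule matching, naive repeat-until-no-change iteration for the belief
fixpoint, subset enumeration of complete extensions for grounded defeat,
direct tallies for merit, pairwise checks for preference, and from-scratch
recomputation for justification closure — at 200+ seeded cases each, with
problem sizes (30-node DAGs, 12-argument graphs, 6-rule bases, 128-trial
decks, 20 seeds) chosen so the whole suite runs in about a minute.

These fixtures emulate the *structure* of the domain — small, noiseless,
fully observed knowledge bases and scenarios whose ground truth the
oracles can enumerate. They do not emulate real clinical knowledge bases
(thousands of concepts, conflicting and uncertain assertions), real
patient data, or human trial-by-trial variability; passing tests show the
kernel computes its stated semantics exactly, not that the semantics fits
any empirical population. In particular the card-sorting lesion results
are qualitative dissociations under the model's own assumptions, not fits
to patient-group statistics.

## Known limitations

* Confidence is ordinal only (`confirmed`/`provisional`/`doubted` tags);
  quantitative uncertainty, probabilistic argument strength and
  expected-utility aggregation are out of scope behind the aggregator
  interface.
* No assumption-based truth maintenance: justification chains are
  well-founded or retracted, with no alternative-context bookkeeping.
* Learning is exactly the two implemented mechanisms (episodic scenario
  records and frequency counters); no generalization over episodes is
  attempted.
* The dialog layer implements the consultation triangle
  (inform/challenge/explain) only — no negotiation or persuasion
  protocols, no concurrency, no transport.
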
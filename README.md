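# dominoagent

An executable kernel for **dynamic decision-making agents** in the domino
(extended belief–desire–intention) tradition, written for computational
cognitive modellers and decision-engineering researchers who want the whole
decision *lifecycle* — not just a choice among fixed options — as runnable,
inspectable code.

Dynamic decision-making starts before any options exist: a situation must
be recognised as demanding a decision, goals raised, candidate solutions
generated, reasons for and against them constructed and weighed,
commitments made (provisionally or firmly), plans enacted, outcomes
monitored, and the knowledge base updated by experience. `dominoagent`
implements this cycle as ten typed cognitive operations over an
ontology-backed, justification-tagged working memory:

| op  | operation            | signature (informally)                               |
|-----|----------------------|------------------------------------------------------|
| S1  | belief maintenance   | Observation × Ontology ⊢ Belief (recursively)        |
| S2  | raising goals        | Belief × Ontology ⊢ Goal; Goal × Ontology ⊢ Goal     |
| S3  | option generation    | Goal × Belief × Ontology ⊢ Candidate                 |
| S4  | constructing reasons | Candidate × Goal × Belief × Ontology ⊢ Candidate × Reason |
| S5  | aggregating reasons  | Goal × Candidate × Reason ⊢ Candidate × Merit        |
| S6  | commitment           | Candidate × Merit × Ontology ⊢ Belief (accept) / Goal × Plan (adopt) |
| S7  | plan enactment       | Goal × Belief × Plan × Ontology ⊢ Goal × Plan        |
| S8  | action               | Plan × Precondition ⊢ Action                         |
| S9  | monitoring           | Goal × Observation × Ontology ⊢ Belief               |
| S10 | learning             | Belief × Ontology ⊢ Scenario; Goal × Belief × Ontology ⊢ Task |

Reasons are handled by **argumentation with defeasible undercutting**:
arguments are instantiated from declarative schemas (pro, con, or
undercut), defeat is resolved by the grounded (skeptical) labelling of the
undercut graph, and merit defaults to the **Bentham rule** — sum the
strengths of the undefeated pros, subtract the undefeated cons — with the
aggregator pluggable per decision. Every working-memory item carries a
justification, so each commitment's full rationale (arguments, labels,
merits) can be read back from the trace.

Two executable scenarios exercise the kernel end to end:

* **Wisconsin Card Sorting Test** — trial-by-trial simulation with a
  simplistic (placement) and a sophisticated (rule-deliberation) strategy,
  expectation monitoring, feedback-driven argument reweighting, and two
  lesion toggles that dissociate perseverative from set-loss errors.
* **A three-agent clinical consultation** — a records agent, a lead
  cardiology agent and a drug-safety specialist jointly choose a treatment
  for a suspected myocardial infarction through switchboard-routed
  performative messages (inform / request / query / challenge / explain),
  with provisional and firm commitment and two learning mechanisms.

Knowledge bases are human-authored YAML (concepts, is-a links, relations,
rules, goal templates, argument schemas, plans, agents); traces are JSONL
and replay bit-identically under a fixed seed.

## Worked example

The single-trial card-sorting walkthrough: the to-be-sorted card shows one
green diamond; target 1 shares its shape and number, target 2 its colour.

```r
library(dominoagent)
we <- wcst_worked_example()
length(we$candidates)   # 4 placement options
length(we$arguments)    # 3 lines of reasoning
we$merits
#> target1 target2 target3 target4
#>       2       1       0       0
we$preference[1]
#> [1] "target1"
```

Two reasons favour target 1 (shape and number match), one favours target 2
(colour), so the Bentham merits are 2 vs 1 and the card goes under
target 1.

The clinical consultation, end to end:

```r
run <- run_mi_scenario(seed = 42)
summarize_trace(run)
#> C decided treatment_decision -> clopidogrel (firm)
#> S decided treatment_decision -> clopidogrel (provisional)
#> messages: 9 | rounds: 11
run$agents$C$history[[1]]$preference[1]   # "aspirin"  (provisional, phase 1)
```

The lead agent first prefers aspirin (effective, available, and modestly
priced: merit 4 vs 3) but, the stakes being high, commits only
provisionally and consults the specialist. The specialist knows aspirin
exacerbates gastritis, finds the patient has gastritis, and prefers
clopidogrel; challenged, it explains with its argument set; the lead agent
incorporates the safety argument (merit 4 − 2 = 2 vs 3), flips to
clopidogrel and commits firmly. An episodic record and a decision-frequency
counter are written.

Card sorting with a lesion toggle:

```r
print(run_wcst(lesion_config(), n_trials = 128, switch_after = 6, seed = 42))
#> wcst: 128 trials, 16 switches; errors: 26 (perseverative 19 , set-loss 0 , other 7 )
print(run_wcst(lesion_config(monitoring = FALSE), n_trials = 128,
               switch_after = 6, seed = 42))
#> wcst: 128 trials, 1 switches; errors: 93 (perseverative 93 , set-loss 0 , other 0 )
```

With expectation monitoring disabled the agent never registers that its
maintained sorting rule has become wrong and perseverates for the rest of
the run.

## Command line

```sh
Rscript inst/cli/dominoagent.R validate --kb inst/extdata/mi.yaml
Rscript inst/cli/dominoagent.R run --kb inst/extdata/mi.yaml --seed 42 --trace mi.jsonl
Rscript inst/cli/dominoagent.R wcst --trials 128 --lesion monitoring --seed 1 --trace wcst.jsonl
Rscript inst/cli/dominoagent.R summarize --trace wcst.jsonl
```

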
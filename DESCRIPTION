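Package: dominoagent
Title: Executable Kernel for Dynamic Decision-Making Agents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An executable agent kernel for dynamic decision-making in the
    domino (extended belief-desire-intention) tradition. Ten typed cognitive
    operations -- belief maintenance, goal raising, option generation,
    argument construction, aggregation of reasons, commitment, plan
    enactment, action, monitoring, and learning -- run over an
    ontology-backed, justification-tagged working memory. Decision options
    are compared by argumentation with defeasible undercutting under grounded
    semantics and a sum-of-reasons (Bentham) aggregation rule. Includes a
    YAML knowledge-base loader, deterministic JSONL trace logging and
    replay, a multi-agent switchboard with performative messaging for joint
    decision-making, a Wisconsin Card Sorting Test simulation with lesion
    toggles, and a three-agent clinical consultation scenario.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
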
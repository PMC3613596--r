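# Small gastro-intestinal demonstration ontology: is-a inheritance,
# causal relations, and a pair of diagnosis rules.
format_version: 1

relations:
  vocabulary: [causes, controls]
  assertions:
    - [gastric_ulcer, causes, hematemesis]
    - [peptic_ulcer, causes, pain_after_meals]

concepts:
  - id: abnormal_state
  - id: disease
    parents: [abnormal_state]
    properties: {has_symptoms: true}
  - id: peptic_ulcer
    parents: [disease]
  - id: gastric_ulcer
    parents: [peptic_ulcer]
  - id: hematemesis
  - id: pain_after_meals

rules:
  - id: r_peptic
    kind: belief
    when: {atom: [indigestion, present]}
    then: [{atom: [possible_diagnosis, peptic_ulcer]}]
  - id: r_gastric
    kind: belief
    when: {and: [{atom: [indigestion, present]}, {atom: [patient, elderly]}]}
    then: [{atom: [possible_diagnosis, gastric_ulcer]}]
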
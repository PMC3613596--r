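# Three-agent clinical consultation knowledge base: a patient-records
# agent, a lead cardiology agent (C) and a drug-safety specialist (S)
# jointly decide the treatment for a suspected myocardial infarction.
format_version: 1

relations:
  vocabulary: [causes, exacerbates, controls, eradicates, effective_for]

concepts:
  - id: abnormal_state
  - id: disease
    parents: [abnormal_state]
    properties: {has_symptoms: true}
  - id: heart_attack
    parents: [disease]
  - id: myocardial_infarction
    parents: [heart_attack]
  - id: gastritis
    parents: [disease]
  - id: treatment
  - id: drug
    parents: [treatment]
  - id: aspirin
    parents: [drug]
    properties: {analgesic: true, anti_clotting: true, available: true,
                 modest_price: true}
  - id: clopidogrel
    parents: [drug]
    properties: {analgesic: true, anti_clotting: true, available: true}
  - id: proton_pump_inhibitor
    parents: [drug]
    properties: {available: true}

goals:
  - id: manage_mi
    condition: {atom: [mi, managed]}
    stakes: high
  - id: prevent_clotting
    condition: {atom: [clotting, prevented]}
  - id: prevent_pain
    condition: {atom: [pain, prevented]}
  - id: treatment_decision
    condition: {atom: [treatment, decided]}
    priority: 2
    stakes: high
    mode: adopt
    consult: S
  # the chronic-pain presentation: two goals are raised at once, to decide
  # the most plausible cause and the most preferred treatment
  - id: decide_cause
    condition: {atom: [cause, decided]}
    mode: accept
    accept_attr: most_plausible_cause
  - id: decide_preferred_treatment
    condition: {atom: [preferred_treatment, decided]}
    mode: adopt

schemas:
  - id: efficacy_analgesia
    polarity: pro
    condition: {property: analgesic}
  - id: efficacy_anticlotting
    polarity: pro
    condition: {property: anti_clotting}
  - id: availability
    polarity: pro
    condition: {property: available}
  - id: price
    polarity: pro
    condition: {property: modest_price}
  # a safety argument outweighs a modest-price argument
  - id: exacerbation
    polarity: con
    strength: 2
    condition: {relation: exacerbates, object_state: present}

rules:
  - id: g_chronic_pain
    kind: goal
    when: {and: [{atom: [pain, severe]}, {atom: [pain, chronic]}]}
    then: [decide_cause, decide_preferred_treatment]

agents:
  - id: records
    roles: [records]
    case: {patient: elderly, chest_pain: present, gastritis: present}
  - id: C
    roles: [lead]
    partition:
      rules:
        - id: b_heart_attack
          kind: belief
          when: {atom: [chest_pain, present]}
          then: [{atom: [possible, heart_attack]}]
        - id: b_mi
          kind: belief
          when: {and: [{atom: [possible, heart_attack]},
                       {atom: [patient, elderly]}]}
          then: [{atom: [possible, myocardial_infarction]}]
        - id: g_manage_mi
          kind: goal
          when: {atom: [possible, myocardial_infarction]}
          then: [manage_mi]
        - id: g_mi_subgoals
          kind: goal
          when_goal: manage_mi
          then: [prevent_clotting, prevent_pain]
        - id: g_mi_treatment
          kind: goal
          when_goal: manage_mi
          then: [treatment_decision]
        - id: c_drugs
          kind: candidate
          when_goal: treatment_decision
          then: [clopidogrel, aspirin]
  - id: S
    roles: [specialist]
    partition:
      relations:
        assertions:
          - [aspirin, exacerbates, gastritis]
      rules:
        - id: c_drugs_s
          kind: candidate
          when_goal: treatment_decision
          then: [aspirin, clopidogrel, proton_pump_inhibitor]

presentations:
  - from: records
    to: C
    facts:
      - {attr: patient, value: elderly}
      - {attr: chest_pain, value: present}
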
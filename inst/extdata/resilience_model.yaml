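# Packaged decision model: three resilience strategies for the national
# healthcare system scored over four criterion dimensions by SMART.
# Dimensions are keyed by the performance-matrix weight vector in row order
# (0.35, 0.30, 0.20, 0.15); the source tables used two conflicting label
# orders for the two single-attribute dimensions with weights 0.35 and 0.20,
# so both variants are recorded (label / alt_label). The rank assignment is
# identical under either labeling.
rank_total: 14
dimensions:
  - id: K1
    label: "Budget allocation"
    alt_label: "Human Resource Management"
    raw_score: 70
  - id: K2
    label: "Healthcare service planning"
    raw_score: 60
  - id: K3
    label: "Human Resource Management"
    alt_label: "Budget allocation"
    raw_score: 40
  - id: K4
    label: "Legal framework"
    raw_score: 30
attributes:
  - id: A3
    dimension_id: K1
    label: "Health system underfunding"
  - id: A2.1
    dimension_id: K2
    label: "Solutions for proper planning and organization of medical services"
  - id: A2.2
    dimension_id: K2
    label: "Educational and informing campaign for the population"
  - id: A2.3
    dimension_id: K2
    label: "Access to medical services for all patients incl. vulnerable groups"
  - id: A2.4
    dimension_id: K2
    label: "Cost-effective alternative solutions, like telemedicine"
  - id: A1
    dimension_id: K3
    label: "Shortage of trained and qualified personnel"
  - id: A4
    dimension_id: K4
    label: "Lack of a harmonized legislation"
alternatives:
  - id: S1
    label: "Prioritization in emergency regime"
    strategy_weight: 0.35
    importance_rank: 1
  - id: S2
    label: "Medium-term solutions"
    strategy_weight: 0.35
    importance_rank: 2
  - id: S3
    label: "Long-term prioritization"
    strategy_weight: 0.35
    importance_rank: 3
ranks:
  S1: {A3: 1, A2.1: 3, A2.2: 1, A2.3: 3, A2.4: 2, A1: 1, A4: 3}
  S2: {A3: 2, A2.1: 2, A2.2: 2, A2.3: 1, A2.4: 3, A1: 2, A4: 2}
  S3: {A3: 3, A2.1: 1, A2.2: 3, A2.3: 2, A2.4: 1, A1: 3, A4: 1}
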
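# Full-pipeline configuration: simulate the default synthetic survey,
# aggregate stage 1, map items onto the decision model's risk/opportunity
# attributes, then run the SMART evaluation and weight sensitivity.
seed: 42
survey:
  source: simulate
  spec: default
  composite_scheme: mean
criteria:
  mapping:
    A3: [Q2.2, Q3.3]          # underfunding: income impact, financing need
    A2.1: [Q2.1, Q2.10]       # service planning/organization
    A2.2: [Q3.1]              # education / screening / vaccination campaigns
    A2.3: [Q2.3]              # access for vulnerable groups
    A2.4: [Q2.4, Q2.6, Q2.7]  # telemedicine as alternative service
    A1: [Q1.1, Q1.2, Q1.12]   # staff overload -> personnel shortage risk
    A4: [Q3.4]                # legal harmonization framework
decision:
  model: packaged
sensitivity:
  delta_grid: [0.01, 0.02, 0.05, 0.1, 0.15, 0.2, 0.3, 0.4, 0.5]
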
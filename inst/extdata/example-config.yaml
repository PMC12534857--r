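# Example parameter configuration: keys are the canonical parameter names
# (see parameter_keys()); anything omitted falls back to the built-in
# base-case fixture. Percent-scaled entries may be written as a
# {value, unit} pair to avoid the classic 100x error.
schema_version: 1

# a cheaper, more sensitive hypothetical cancer biomarker
cancer_test_cost: 25
cancer_sensitivity: 0.45

discount_rate:
  value: 3.5
  unit: percent

ranges:
  cancer_sensitivity:
    low: 0.35
    high: 0.80
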
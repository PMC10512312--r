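# Shipped defaults for the bgcrank aggregation schemes.
# Percent-match bins for predicted antimicrobial peptides: half-open
# [lower, upper) intervals with an exact top bin; values strictly below the
# exclusion threshold are dropped from all analyses.
bins:
  exclusion_threshold: 51.0
  intervals:
    - {label: "100",        lower: 100, upper: 100, lower_inclusive: true, upper_inclusive: true}
    - {label: "99.9–95.0",  lower: 95,  upper: 100, lower_inclusive: true, upper_inclusive: false}
    - {label: "94.9–90.0",  lower: 90,  upper: 95,  lower_inclusive: true, upper_inclusive: false}
    - {label: "89.9–80.0",  lower: 80,  upper: 90,  lower_inclusive: true, upper_inclusive: false}
    - {label: "79.9–70",    lower: 70,  upper: 80,  lower_inclusive: true, upper_inclusive: false}
    - {label: "69.9–51.0",  lower: 51,  upper: 70,  lower_inclusive: true, upper_inclusive: false}

# Annotation keyword categories, matched in order (first match wins),
# case-insensitive substrings; unmatched annotations fall back.
keywords:
  fallback_label: other
  categories:
    "hypothetical protein": ["hypothetical protein"]
    "glycoside hydrolase family": ["glycoside hydrolase"]
    "cytochrome P450 family": ["cytochrome p450", "p450"]
    "non-ribosomal peptide synthetase": ["non-ribosomal peptide synthetase", "nonribosomal peptide", "nrps"]
    "ABC transporter": ["abc transporter"]
    "glycosyltransferase": ["glycosyltransferase"]
    "peptidase": ["peptidase"]

pagerank:
  damping: 0.85
  tolerance: 1.0e-10
  max_iterations: 1000
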
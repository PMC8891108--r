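# Default ADMET scoring rubric (version 1).
#
# Each entry maps one predicted parameter to its category and a scoring
# rule on the 0 (worst) .. 30 (optimal) scale:
#   - categorical parameters: `map` of level -> score
#   - numeric parameters: `values`/`scores` anchor points; raw values are
#     linearly interpolated between anchors and clamped outside them.
# These defaults cover common in-silico ADMET outputs; analyses that need
# reproducible scores should pin their own rubric file rather than rely on
# these defaults.

molecular_weight:
  category: physicochemical
  values: [100, 300, 500, 700]
  scores: [20, 30, 30, 0]
tpsa:
  category: physicochemical
  values: [0, 140, 200]
  scores: [30, 30, 0]
consensus_logp:
  category: physicochemical
  values: [-2, 0, 3, 5, 7]
  scores: [0, 20, 30, 10, 0]
solubility_class:
  category: physicochemical
  map:
    Insoluble: 0
    "Poorly soluble": 5
    "Moderately soluble": 15
    Soluble: 25
    "Very soluble": 30
    "Highly soluble": 30

gi_absorption:
  category: pharmacokinetics
  map:
    High: 30
    Low: 0
bbb_permeant:
  category: pharmacokinetics
  map:
    "No": 30
    "Yes": 10
pgp_substrate:
  category: pharmacokinetics
  map:
    "No": 30
    "Yes": 10
cyp3a4_inhibitor:
  category: pharmacokinetics
  map:
    "No": 30
    "Yes": 0

lipinski_violations:
  category: drug-likeness
  values: [0, 1, 2, 3, 4]
  scores: [30, 20, 10, 5, 0]
veber_violations:
  category: drug-likeness
  values: [0, 1, 2]
  scores: [30, 15, 0]

pains_alerts:
  category: medicinal chemistry
  values: [0, 1, 2, 3]
  scores: [30, 10, 5, 0]
synthetic_accessibility:
  category: medicinal chemistry
  values: [1, 5, 10]
  scores: [30, 20, 0]

bioavailability_score:
  category: bioavailability
  values: [0.11, 0.55, 0.85]
  scores: [0, 25, 30]
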
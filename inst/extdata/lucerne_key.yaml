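# Dichotomous identification key to the contemporary whitefish species of
# Lake Lucerne. Quantities "X/Y" are raw ratios of two measured characters
# (identical whether computed from mm or from percent values sharing one
# denominator is NOT assumed: they are evaluated on mm); bare quantities
# are percent-standardized characters (DFAe, %SL) or meristic counts
# (totalGR). The key reaches C. nobilis by two distinct paths (couplets 3
# and 5), so it must be followed completely to separate C. nobilis from
# the other species.
entry: 1
couplets:
  - id: 1
    alternatives:
      - conditions:
          - {quantity: "PreD/ED", min: 10.73, max: 12.75}
        outcome: {couplet: 2}
      - conditions:
          - {quantity: "PreD/ED", min: 8.17, max: 10.59}
        outcome: {couplet: 4}
  - id: 2
    alternatives:
      - conditions:
          - {quantity: "totalGR", min: 24, max: 32}
        outcome: {species: "C.litoralis"}
      - conditions:
          - {quantity: "totalGR", min: 33, max: 40}
        outcome: {couplet: 3}
  - id: 3
    alternatives:
      - conditions:
          - {quantity: "PecFB/CD", min: 0.41, max: 0.43}
        outcome: {species: "C.suspensus"}
      - conditions:
          - {quantity: "PecFB/CD", min: 0.45, max: 0.52}
        outcome: {species: "C.nobilis"}
  - id: 4
    alternatives:
      - conditions:
          - {quantity: "TL/ED", min: 21.37, max: 24.45}
        outcome: {species: "C.muelleri"}
      - conditions:
          - {quantity: "TL/ED", min: 24.5, max: 29.59}
        outcome: {couplet: 5}
  - id: 5
    alternatives:
      - conditions:
          - {quantity: "CD/HW", min: 0.77, max: 0.87}
          - {quantity: "DFAe", min: 17.3, max: 19.9}
        outcome: {species: "C.intermundia"}
      - conditions:
          - {quantity: "CD/HW", min: 0.63, max: 0.77}
          - {quantity: "DFAe", min: 15.3, max: 17.2}
        outcome: {species: "C.nobilis"}
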
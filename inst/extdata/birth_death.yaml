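# Minimal one-species birth-death network: constant production,
# first-order degradation. Used in examples and IO tests.
name: birth_death
species: [x1]
bounds:
  lower: [0]
  upper: [40]
parameters:
  k: 8
  gamma: 1
domain:
  k: [4, 16]
reactions:
  - name: birth
    reactant: [0]
    product: [1]
  - name: death
    reactant: [1]
    product: [0]
propensities:
  - reaction: 1
    coef: k
    state: "1"
    label: k
  - reaction: 2
    coef: gamma
    state: x1
    label: gamma
init: "x1 == 0"
T: 4
units: a.u.
outputs:
  - kind: expectation
    species: x1
  - kind: region
    predicate: "x1 > 5"
    label: "Prob(x1 > 5)"
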
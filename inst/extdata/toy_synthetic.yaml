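# Minimal single-input walker circuit on a 7 x 8 grid (synthetic
# illustration fixture): INIT -> fork; the upper branch (label x) leads
# to the true final, the lower branch (label !x) to the false final.
inputs:
- x
function: x
vertices:
- id: v0
  x: 4
  y: 1
  type: INIT
  label: eps
- id: f
  x: 4
  y: 3
  type: FORK
  label: eps
- id: a
  x: 2
  y: 5
  type: NORM
  label: x
- id: b
  x: 6
  y: 5
  type: NORM
  label: '!x'
- id: fT
  x: 2
  y: 7
  type: FINAL
  label: eps
  out: T
- id: fF
  x: 6
  y: 7
  type: FINAL
  label: eps
  out: F
edges:
- - v0
  - f
- - f
  - a
- - f
  - b
- - a
  - fT
- - b
  - fF
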
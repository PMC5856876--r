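# Synthetic reconstruction of a grid layout for the Boolean function
# x | y | z as a binary decision DAG (3 forks, 2 joins, true/false
# finals).  Compact packing: parallel tracks sit within interaction range, producing many leakage transitions.
# Coordinates were fitted so the 12-cell transition classification
# table reproduces the reference profile for this design style.
inputs:
- x
- 'y'
- z
function: x | y | z
vertices:
- id: x5
  x: 1
  'y': 7
  type: NORM
  label: eps
- id: x6
  x: 1
  'y': 9
  type: NORM
  label: eps
- id: x7
  x: 1
  'y': 12
  type: NORM
  label: eps
- id: x8
  x: 1
  'y': 13
  type: NORM
  label: eps
- id: x4
  x: 2
  'y': 4
  type: NORM
  label: eps
- id: x2
  x: 3
  'y': 2
  type: NORM
  label: eps
- id: x3
  x: 3
  'y': 6
  type: NORM
  label: eps
- id: J1
  x: 3
  'y': 15
  type: JOIN
  label: eps
- id: i1
  x: 3
  'y': 17
  type: NORM
  label: eps
- id: y4
  x: 4
  'y': 13
  type: NORM
  label: eps
- id: i2
  x: 4
  'y': 19
  type: NORM
  label: eps
- id: x1
  x: 5
  'y': 2
  type: NORM
  label: x
- id: fT
  x: 5
  'y': 23
  type: FINAL
  label: eps
  out: T
- id: y3
  x: 6
  'y': 12
  type: NORM
  label: eps
- id: z4
  x: 6
  'y': 18
  type: NORM
  label: eps
- id: J2
  x: 6
  'y': 20
  type: JOIN
  label: eps
- id: j1
  x: 6
  'y': 22
  type: NORM
  label: eps
- id: fA
  x: 7
  'y': 2
  type: FORK
  label: eps
- id: v0
  x: 8
  'y': 1
  type: INIT
  label: eps
- id: y2
  x: 8
  'y': 12
  type: NORM
  label: eps
- id: z3
  x: 8
  'y': 17
  type: NORM
  label: eps
- id: nx1
  x: 9
  'y': 4
  type: NORM
  label: '!x'
- id: y1
  x: 10
  'y': 10
  type: NORM
  label: 'y'
- id: z2
  x: 10
  'y': 15
  type: NORM
  label: eps
- id: nx2
  x: 12
  'y': 4
  type: NORM
  label: eps
- id: nx3
  x: 12
  'y': 6
  type: NORM
  label: eps
- id: fB
  x: 12
  'y': 8
  type: FORK
  label: eps
- id: ny1
  x: 12
  'y': 11
  type: NORM
  label: '!y'
- id: z1
  x: 12
  'y': 16
  type: NORM
  label: z
- id: nz1
  x: 13
  'y': 16
  type: NORM
  label: '!z'
- id: nz2
  x: 13
  'y': 19
  type: NORM
  label: eps
- id: ny2
  x: 14
  'y': 12
  type: NORM
  label: eps
- id: fC
  x: 14
  'y': 15
  type: FORK
  label: eps
- id: fF
  x: 14
  'y': 26
  type: FINAL
  label: eps
  out: F
- id: nz4
  x: 16
  'y': 19
  type: NORM
  label: eps
- id: nz9
  x: 17
  'y': 26
  type: NORM
  label: eps
- id: nz6
  x: 19
  'y': 19
  type: NORM
  label: eps
- id: nz3
  x: 19
  'y': 21
  type: NORM
  label: eps
- id: nz8
  x: 19
  'y': 28
  type: NORM
  label: eps
- id: nz7
  x: 20
  'y': 23
  type: NORM
  label: eps
- id: nz10
  x: 20
  'y': 25
  type: NORM
  label: eps
- id: nz5
  x: 20
  'y': 28
  type: NORM
  label: eps
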
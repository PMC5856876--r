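# Synthetic reconstruction of a grid layout for the Boolean function
# x | y | z as a binary decision DAG (3 forks, 2 joins, true/false
# finals).  Spread packing: larger branch separation removes most leakage transitions at the cost of area and track length.
# Coordinates were fitted so the 12-cell transition classification
# table reproduces the reference profile for this design style.
inputs:
- x
- 'y'
- z
function: x | y | z
vertices:
- id: x8
  x: 1
  'y': 5
  type: NORM
  label: eps
- id: x2
  x: 1
  'y': 7
  type: NORM
  label: eps
- id: x9
  x: 1
  'y': 11
  type: NORM
  label: eps
- id: x6
  x: 2
  'y': 10
  type: NORM
  label: eps
- id: x4
  x: 3
  'y': 3
  type: NORM
  label: eps
- id: x7
  x: 3
  'y': 8
  type: NORM
  label: eps
- id: J1
  x: 3
  'y': 13
  type: JOIN
  label: eps
- id: i1
  x: 4
  'y': 15
  type: NORM
  label: eps
- id: x5
  x: 5
  'y': 3
  type: NORM
  label: eps
- id: y5
  x: 5
  'y': 12
  type: NORM
  label: eps
- id: i2
  x: 5
  'y': 17
  type: NORM
  label: eps
- id: y4
  x: 6
  'y': 11
  type: NORM
  label: eps
- id: fT
  x: 6
  'y': 23
  type: FINAL
  label: eps
  out: T
- id: x3
  x: 7
  'y': 3
  type: NORM
  label: eps
- id: J2
  x: 7
  'y': 19
  type: JOIN
  label: eps
- id: j1
  x: 7
  'y': 21
  type: NORM
  label: eps
- id: x1
  x: 9
  'y': 4
  type: NORM
  label: x
- id: y3
  x: 9
  'y': 11
  type: NORM
  label: eps
- id: v0
  x: 10
  'y': 1
  type: INIT
  label: eps
- id: z5
  x: 10
  'y': 19
  type: NORM
  label: eps
- id: fA
  x: 11
  'y': 3
  type: FORK
  label: eps
- id: y2
  x: 11
  'y': 9
  type: NORM
  label: eps
- id: nx1
  x: 13
  'y': 5
  type: NORM
  label: '!x'
- id: y1
  x: 13
  'y': 9
  type: NORM
  label: 'y'
- id: z4
  x: 13
  'y': 19
  type: NORM
  label: eps
- id: nx2
  x: 14
  'y': 6
  type: NORM
  label: eps
- id: fB
  x: 15
  'y': 10
  type: FORK
  label: eps
- id: ny1
  x: 15
  'y': 11
  type: NORM
  label: '!y'
- id: z3
  x: 15
  'y': 19
  type: NORM
  label: eps
- id: nx3
  x: 16
  'y': 8
  type: NORM
  label: eps
- id: z2
  x: 17
  'y': 17
  type: NORM
  label: eps
- id: ny2
  x: 18
  'y': 11
  type: NORM
  label: eps
- id: z1
  x: 19
  'y': 15
  type: NORM
  label: z
- id: fC
  x: 20
  'y': 13
  type: FORK
  label: eps
- id: nz1
  x: 23
  'y': 13
  type: NORM
  label: '!z'
- id: nz3
  x: 23
  'y': 16
  type: NORM
  label: eps
- id: nz2
  x: 25
  'y': 9
  type: NORM
  label: eps
- id: nz4
  x: 26
  'y': 8
  type: NORM
  label: eps
- id: nz7
  x: 26
  'y': 16
  type: NORM
  label: eps
- id: fF
  x: 27
  'y': 6
  type: FINAL
  label: eps
  out: F
- id: nz6
  x: 27
  'y': 11
  type: NORM
  label: eps
- id: nz5
  x: 27
  'y': 13
  type: NORM
  label: eps
- id: nz8
  x: 27
  'y': 15
  type: NORM
  label: eps
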
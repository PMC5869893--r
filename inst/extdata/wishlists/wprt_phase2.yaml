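# Phase 2 sequential prostate boost (13 Gy in 5 fx).  All percentages
# resolve against the boost prescription D_p.
name: wprt_phase2
phase: 2
auxiliary:
- name: femoral_heads
  recipe: union
  of: [femoral_head_left, femoral_head_right]
- name: PTV-P shell 5 mm
  recipe: shell
  of: PTV-P
  distance_mm: 5.0
  thickness_mm: 5.0
  exclude: PTV-P
- name: PTV-P shell 15 mm
  recipe: shell
  of: PTV-P
  distance_mm: 15.0
  thickness_mm: 5.0
  exclude: PTV-P
- name: PTV-P shell 25 mm
  recipe: shell
  of: PTV-P
  distance_mm: 25.0
  thickness_mm: 5.0
  exclude: PTV-P
- name: PTV-P shell 50 mm
  recipe: shell
  of: PTV-P
  distance_mm: 50.0
  thickness_mm: 5.0
  exclude: PTV-P
- name: Skin ring 20 mm
  recipe: ring
  depth_mm: 20.0
  exclude: PTV-P
- name: Unspecified tissues
  recipe: unspecified
constraints:
- structure: PTV-P
  type: MAX
  limit: {percent: 105.0, of: D_p}
- structure: PTV-P
  type: MEAN
  limit: {percent: 101.0, of: D_p}
- structure: femoral_heads
  type: MAX
  limit: {percent: 70.0, of: D_p}
- structure: PTV-P shell 50 mm
  type: MAX
  limit: {percent: 50.0, of: D_p}
- structure: Unspecified tissues
  type: MAX
  limit: {percent: 105.0, of: D_p}
objectives:
- priority: 1
  structure: PTV-P
  kind: LTCP
  goal: 0.5
  params:
    D_p: {percent: 100.0, of: D_p}
    alpha: 0.95
- priority: 2
  structure: PTV-P shell 5 mm
  kind: MAX
  goal: {percent: 90.0, of: D_p}
- priority: 3
  structure: rectum
  kind: EUD
  goal: {percent: 70.0, of: D_p}
  params: {k: 16.0}
- priority: 4
  structure: bladder
  kind: EUD
  goal: {percent: 60.0, of: D_p}
  params: {k: 12.0}
- priority: 5
  structure: PTV-P shell 15 mm
  kind: MAX
  goal: {percent: 50.0, of: D_p}
- priority: 5
  structure: PTV-P shell 25 mm
  kind: MAX
  goal: {percent: 30.0, of: D_p}
- priority: 5
  structure: Skin ring 20 mm
  kind: MAX
  goal: {percent: 30.0, of: D_p}
- priority: 6
  structure: rectum
  kind: MEAN
  goal: {percent: 10.0, of: D_p}
- priority: 7
  structure: bladder
  kind: MEAN
  goal: {percent: 10.0, of: D_p}
- priority: 8
  structure: femoral_heads
  kind: EUD
  goal: {percent: 10.0, of: D_p}
  params: {k: 5.0}
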
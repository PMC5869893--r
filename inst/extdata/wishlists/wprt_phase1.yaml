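# Whole-pelvis phase 1 (simultaneous integrated boost, 60/50 Gy in 25 fx).
# Hard constraints are inviolable; objectives are minimized in priority
# order, rows sharing a priority in listed order.
name: wprt_phase1
phase: 1
auxiliary:
- name: femoral_heads
  recipe: union
  of: [femoral_head_left, femoral_head_right]
- name: PTV-P+5mm
  recipe: expand
  of: PTV-P
  margin_mm: 5.0
- name: PTV-LN - PTV-P+5mm
  recipe: subtract
  of: PTV-LN
  minus: PTV-P+5mm
- name: PTV-LN shell 5 mm
  recipe: shell
  of: PTV-LN
  distance_mm: 5.0
  thickness_mm: 5.0
  exclude: PTV-LN
- name: PTV-LN shell 15 mm
  recipe: shell
  of: PTV-LN
  distance_mm: 15.0
  thickness_mm: 5.0
  exclude: PTV-LN
- name: PTV-LN shell 25 mm
  recipe: shell
  of: PTV-LN
  distance_mm: 25.0
  thickness_mm: 5.0
  exclude: PTV-LN
- name: PTV-LN shell 50 mm
  recipe: shell
  of: PTV-LN
  distance_mm: 50.0
  thickness_mm: 5.0
  exclude: PTV-LN
- name: Skin ring 20 mm
  recipe: ring
  depth_mm: 20.0
  exclude: PTV-LN
- name: Unspecified tissues
  recipe: unspecified
constraints:
- structure: PTV-P
  type: MAX
  limit: {percent: 105.0, of: D_high}
- structure: PTV-P
  type: MEAN
  limit: {percent: 101.0, of: D_high}
- structure: PTV-LN - PTV-P+5mm
  type: MAX
  limit: {percent: 105.0, of: D_low}
- structure: PTV-LN - PTV-P+5mm
  type: MEAN
  limit: {percent: 101.0, of: D_low}
- structure: femoral_heads
  type: MAX
  limit: {percent: 70.0, of: D_high}
- structure: PTV-LN shell 50 mm
  type: MAX
  limit: {percent: 50.0, of: D_high}
- structure: Unspecified tissues
  type: MAX
  limit: {percent: 105.0, of: D_high}
objectives:
- priority: 1
  structure: PTV-P
  kind: LTCP
  goal: 0.65
  params:
    D_p: {percent: 100.0, of: D_high}
    alpha: 0.7
- priority: 2
  structure: PTV-LN
  kind: LTCP
  goal: 0.5
  params:
    D_p: {percent: 100.0, of: D_low}
    alpha: 0.9
- priority: 3
  structure: PTV-LN shell 5 mm
  kind: MAX
  goal: {percent: 90.0, of: D_low}
- priority: 4
  structure: rectum
  kind: EUD
  goal: {percent: 70.0, of: D_high}
  params: {k: 12.0}
- priority: 4
  structure: rectum
  kind: EUD
  goal: {percent: 30.0, of: D_high}
  params: {k: 4.0}
- priority: 5
  structure: bladder
  kind: EUD
  goal: {percent: 30.0, of: D_high}
  params: {k: 4.0}
- priority: 6
  structure: PTV-LN shell 15 mm
  kind: MAX
  goal: {percent: 60.0, of: D_low}
- priority: 6
  structure: PTV-LN shell 25 mm
  kind: MAX
  goal: {percent: 40.0, of: D_low}
- priority: 7
  structure: bowel_bag
  kind: EUD
  goal: {percent: 30.0, of: D_high}
  params: {k: 8.0}
- priority: 8
  structure: Skin ring 20 mm
  kind: MAX
  goal: {percent: 30.0, of: D_high}
- priority: 9
  structure: rectum
  kind: MEAN
  goal: {percent: 20.0, of: D_low}
- priority: 10
  structure: bladder
  kind: MEAN
  goal: {percent: 20.0, of: D_low}
- priority: 11
  structure: bowel_bag
  kind: MEAN
  goal: {percent: 20.0, of: D_low}
- priority: 12
  structure: femoral_heads
  kind: EUD
  goal: {percent: 10.0, of: D_high}
  params: {k: 5.0}
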
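units:
  length: cm
  area: cm2
  beta: dyn/cm
  resistance: mmHg.s/mL
  compliance: mL/mmHg
  pressure: mmHg
  flow: mL/s
  time: s
vessels:
- id: asc_ao
  length: 4.0
  area_prox: 4.9
  area_dist: 4.5
  beta: 1015268.0
- id: arch
  length: 4.0
  area_prox: 4.3
  area_dist: 3.9
  beta: 1030671.0
- id: thor_ao
  length: 16.0
  area_prox: 3.5
  area_dist: 2.4
  beta: 984586.0
- id: abd_ao1
  length: 3.5
  area_prox: 1.76
  area_dist: 1.6
  beta: 924371.0
- id: abd_ao2
  length: 3.5
  area_prox: 1.6
  area_dist: 1.45
  beta: 911328.0
- id: abd_ao3
  length: 3.5
  area_prox: 1.45
  area_dist: 1.26
  beta: 888399.0
- id: abd_ao4
  length: 3.5
  area_prox: 1.26
  area_dist: 1.09
  beta: 883361.0
- id: visceral
  length: 6.0
  area_prox: 0.8
  area_dist: 0.7
  beta: 660951.0
- id: cca_r1
  length: 8.9
  area_prox: 0.5
  area_dist: 0.44
  beta: 614061.0
- id: cca_r2
  length: 8.9
  area_prox: 0.44
  area_dist: 0.38
  beta: 627691.0
- id: cca_l1
  length: 8.9
  area_prox: 0.5
  area_dist: 0.44
  beta: 614061.0
- id: cca_l2
  length: 8.9
  area_prox: 0.44
  area_dist: 0.38
  beta: 627691.0
- id: sub_r1
  length: 3.4
  area_prox: 0.55
  area_dist: 0.5
  beta: 710286.0
- id: sub_r2
  length: 6.8
  area_prox: 0.5
  area_dist: 0.42
  beta: 704548.0
- id: sub_l1
  length: 3.4
  area_prox: 0.55
  area_dist: 0.5
  beta: 710286.0
- id: sub_l2
  length: 6.8
  area_prox: 0.5
  area_dist: 0.42
  beta: 704548.0
- id: brachial_r
  length: 22.0
  area_prox: 0.4
  area_dist: 0.28
  beta: 695341.0
- id: brachial_l
  length: 22.0
  area_prox: 0.4
  area_dist: 0.28
  beta: 695341.0
- id: radial_r
  length: 23.0
  area_prox: 0.12
  area_dist: 0.08
  beta: 543026.0
- id: radial_l
  length: 23.0
  area_prox: 0.12
  area_dist: 0.08
  beta: 543026.0
- id: com_iliac_r
  length: 5.9
  area_prox: 0.6
  area_dist: 0.52
  beta: 777367.0
- id: com_iliac_l
  length: 5.9
  area_prox: 0.6
  area_dist: 0.52
  beta: 777367.0
- id: ext_iliac_r
  length: 14.4
  area_prox: 0.42
  area_dist: 0.34
  beta: 735106.0
- id: ext_iliac_l
  length: 14.4
  area_prox: 0.42
  area_dist: 0.34
  beta: 735106.0
- id: femoral1_r
  length: 12.7
  area_prox: 0.32
  area_dist: 0.26
  beta: 730659.0
- id: femoral1_l
  length: 12.7
  area_prox: 0.32
  area_dist: 0.26
  beta: 730659.0
- id: femoral2_r
  length: 12.7
  area_prox: 0.26
  area_dist: 0.22
  beta: 750377.0
- id: femoral2_l
  length: 12.7
  area_prox: 0.26
  area_dist: 0.22
  beta: 750377.0
- id: popliteal_r
  length: 9.4
  area_prox: 0.22
  area_dist: 0.18
  beta: 767955.0
- id: popliteal_l
  length: 9.4
  area_prox: 0.22
  area_dist: 0.18
  beta: 767955.0
junctions:
- parent: asc_ao
  children:
  - arch
  - cca_r1
  - cca_l1
- parent: arch
  children:
  - thor_ao
  - sub_r1
  - sub_l1
- parent: thor_ao
  children:
  - abd_ao1
  - visceral
- parent: abd_ao1
  children: abd_ao2
- parent: abd_ao2
  children: abd_ao3
- parent: abd_ao3
  children: abd_ao4
- parent: abd_ao4
  children:
  - com_iliac_r
  - com_iliac_l
- parent: cca_r1
  children: cca_r2
- parent: cca_l1
  children: cca_l2
- parent: sub_r1
  children: sub_r2
- parent: sub_l1
  children: sub_l2
- parent: sub_r2
  children: brachial_r
- parent: sub_l2
  children: brachial_l
- parent: brachial_r
  children: radial_r
- parent: brachial_l
  children: radial_l
- parent: com_iliac_r
  children: ext_iliac_r
- parent: com_iliac_l
  children: ext_iliac_l
- parent: ext_iliac_r
  children: femoral1_r
- parent: ext_iliac_l
  children: femoral1_l
- parent: femoral1_r
  children: femoral2_r
- parent: femoral1_l
  children: femoral2_l
- parent: femoral2_r
  children: popliteal_r
- parent: femoral2_l
  children: popliteal_l
inlet:
  vessel: asc_ao
  period: 0.9
  waveform:
    type: half_sine
    mean_flow: 90.0
    systole_fraction: 0.3333
outlets:
  visceral:
    R1: 0.5988
    R2: 1.7963
    C: 0.36
    p_out: 0.0
  cca_r2:
    R1: 1.4228
    R2: 12.0494
    C: 0.064
    p_out: 0.0
  cca_l2:
    R1: 1.4228
    R2: 12.0494
    C: 0.064
    p_out: 0.0
  radial_r:
    R1: 3.8492
    R2: 11.5476
    C: 0.056
    p_out: 0.0
  radial_l:
    R1: 3.8492
    R2: 11.5476
    C: 0.056
    p_out: 0.0
  popliteal_r:
    R1: 2.1556
    R2: 6.4666
    C: 0.1
    p_out: 0.0
  popliteal_l:
    R1: 2.1556
    R2: 6.4666
    C: 0.1
    p_out: 0.0
chains:
- name: CA
  side: right
  segments:
  - cca_r1
  - cca_r2
- name: CA
  side: left
  segments:
  - cca_l1
  - cca_l2
- name: SA
  side: right
  segments:
  - sub_r1
  - sub_r2
- name: SA
  side: left
  segments:
  - sub_l1
  - sub_l2
- name: PA
  side: right
  segments:
  - com_iliac_r
  - ext_iliac_r
  - femoral1_r
  - femoral2_r
  - popliteal_r
- name: PA
  side: left
  segments:
  - com_iliac_l
  - ext_iliac_l
  - femoral1_l
  - femoral2_l
  - popliteal_l
- name: AA
  side: none
  segments:
  - abd_ao1
  - abd_ao2
  - abd_ao3
  - abd_ao4
sites:
- name: P1
  side: right
  vessel: cca_r2
  position: 0.5
  quantity: pressure
- name: P1
  side: left
  vessel: cca_l2
  position: 0.5
  quantity: pressure
- name: P2
  side: right
  vessel: brachial_r
  position: 0.5
  quantity: pressure
- name: P2
  side: left
  vessel: brachial_l
  position: 0.5
  quantity: pressure
- name: P3
  side: right
  vessel: radial_r
  position: 0.5
  quantity: pressure
- name: P3
  side: left
  vessel: radial_l
  position: 0.5
  quantity: pressure
- name: Q1
  side: right
  vessel: cca_r2
  position: 0.5
  quantity: flow
- name: Q1
  side: left
  vessel: cca_l2
  position: 0.5
  quantity: flow
- name: Q2
  side: right
  vessel: brachial_r
  position: 0.5
  quantity: flow
- name: Q2
  side: left
  vessel: brachial_l
  position: 0.5
  quantity: flow
- name: Q3
  side: right
  vessel: femoral1_r
  position: 0.5
  quantity: flow
- name: Q3
  side: left
  vessel: femoral1_l
  position: 0.5
  quantity: flow
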
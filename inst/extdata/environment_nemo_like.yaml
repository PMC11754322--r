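# Synthetic free-exploration environment in the style of a 140 x 140 vm
# island with 20 landmarks on a regular lattice.  Distances in vm.
name: nemo_like_synthetic
bounds: [0, 0, 140, 140]
bin_size: 14
k_norm: 100
landmarks:
  - {id: L01, x: 14, y: 14}
  - {id: L02, x: 42, y: 14}
  - {id: L03, x: 70, y: 14}
  - {id: L04, x: 98, y: 14}
  - {id: L05, x: 126, y: 14}
  - {id: L06, x: 14, y: 42}
  - {id: L07, x: 42, y: 42}
  - {id: L08, x: 70, y: 42}
  - {id: L09, x: 98, y: 42}
  - {id: L10, x: 126, y: 42}
  - {id: L11, x: 14, y: 70}
  - {id: L12, x: 42, y: 70}
  - {id: L13, x: 70, y: 70}
  - {id: L14, x: 98, y: 70}
  - {id: L15, x: 126, y: 70}
  - {id: L16, x: 14, y: 98}
  - {id: L17, x: 42, y: 98}
  - {id: L18, x: 70, y: 98}
  - {id: L19, x: 98, y: 98}
  - {id: L20, x: 126, y: 98}
params:
  rediscretize_step: 0.48
  rdp_epsilon: 6
  flight_turn_cutoff: 160
  landmark_radius: 20
  revisit_radius: 14
  target_hz: 10
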
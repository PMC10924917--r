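# Desk-scale demo of the virtual-histology pipeline: a small 2D phantom
# scanned under the 4 um / 500 mm protocol preset (reduced angle count and
# grid so the demo runs in seconds).
seed: 7
phantom:
  shape: [128, 128]
  voxel_um: 4
  n_adipocytes: 3
  adipocyte_r_um: [20, 40]
  n_ducts: 1
  duct_r_um: [25, 35]
  n_calcifications: 1
  calc_r_um: [8, 14]
  n_bubbles: 1
  bubble_r_um: [10, 16]
  stroma_fraction: 0
  tissue_radius_frac: 0.68
  edge_sigma_px: 1
scan:
  pixel_um: 4
  distance_mm: 500
  energy_keV: 20
  n_proj: 200
  det_width: 128
  det_height: 1
detector:
  n0: 5000
  dark_level: 20
  dark_sigma: 1
  gain_sigma: 0.01
  gain_drift_sigma: 0.02
  psf_sigma_px: 0.6
  noise: true
  beam_hardening: 2
preprocess:
  ring_window: 9
phase_retrieval:
  delta_beta: 350
enhance:
  detrend: true
  unsharp_amount: 1
  unsharp_sigma: 2
register:
  depth: 1
  theta_deg: 3
  t_row: 2
  t_col: -3
  dropout_frac: 0.05
  theta_range: [-6, 6]
  theta_step: 1
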
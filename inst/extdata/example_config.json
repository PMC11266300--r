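{
  "seed": 1,
  "output_dir": "ssm_output",
  "parameters": {
    "threshold": 350,
    "kernel_mm": 3.0,
    "target_edge": 2.0,
    "nn_mode": "vertex",
    "n_modes": 5,
    "mesh_spacing": 1.5
  },
  "groups": [
    { "name": "complete_femur_group_1", "side": "left" },
    { "name": "complete_femur_group_1", "side": "right" },
    { "name": "complete_femur_group_2", "side": "left" },
    { "name": "complete_femur_group_3", "side": "left" },
    { "name": "complete_femur_group_4", "side": "left" },
    { "name": "complete_femur_group_5", "side": "left" },
    { "name": "complete_femur_group_6", "side": "left" },
    { "name": "femur_condyles", "side": "left" },
    { "name": "femoral_head", "side": "left" },
    { "name": "tibia", "side": "left" },
    { "name": "tibia_plateau", "side": "left" },
    { "name": "patella", "side": "left" }
  ]
}
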
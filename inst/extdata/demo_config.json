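{
  "preset": "deltaMukB",
  "mode": "phenomenological",
  "layout": "mother_machine",
  "n_lineages": 6,
  "duration": 1080,
  "frame_interval": 5,
  "seed": 7,
  "stages": ["lineage", "organization", "flipping", "colocalization", "retention"],
  "out_dir": "demo_output"
}
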
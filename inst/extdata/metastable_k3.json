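{
  "description": "Small three-state metastable dimer fixture used by the end-to-end report tests: persistent cyclic chain, state separation well above the 2.0 Angstrom cluster cutoff.",
  "generator": "simulateMetastable",
  "template": {"nResPerHelix": 10, "gaugeSeparation": 12.5, "nLoopRes": 3},
  "K": 3,
  "switchProb": 0.05,
  "sigma": 0.3,
  "nFrames": 300,
  "seed": 1,
  "rmsdFloor": 6,
  "dt": 1
}
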
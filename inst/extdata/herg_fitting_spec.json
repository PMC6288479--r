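{
  "algorithm": "AdaptiveMCMC",
  "arguments": {
    "cmaOpt": 5,
    "cmaMaxFevals": 20000,
    "burn": 50000,
    "numIters": 100000
  },
  "output": {
    "exp_IKr": "IKr"
  },
  "input": {
    "exp_times": "t"
  },
  "prior": {
    "kO1": [1e-7, 0.1],
    "kO2": [1e-7, 0.1],
    "kC1": [1e-7, 0.1],
    "kC2": [1e-7, 0.1],
    "kI1": [1e-7, 0.1],
    "kI2": [1e-7, 0.1],
    "kA1": [1e-7, 0.1],
    "kA2": [1e-7, 0.1],
    "GKr": [0.0612, 0.612],
    "obj:std": 0.00463
  },
  "units": {
    "t": "s",
    "exp_IKr": "nA"
  }
}
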
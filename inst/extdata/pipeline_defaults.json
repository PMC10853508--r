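{
  "nChannels": 54,
  "sampleRate": 30,
  "totalDuration": 180,
  "taskEpoch": 18,
  "restEpoch": 12,
  "nTD": 19,
  "nASD": 17,
  "nPC": 32,
  "k": 10,
  "mode": "nested",
  "C": 1,
  "nPerm": 1000,
  "alphas": [0.05, 0.005],
  "cutoffPeriod": 128,
  "hrf": {
    "peakDelay": 6,
    "undershootDelay": 16,
    "peakDispersion": 1,
    "undershootDispersion": 1,
    "ratio": 6,
    "kernelLength": 32
  }
}
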
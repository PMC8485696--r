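# Small demonstration pipeline: an 8-participant synthetic cohort with one
# planted long-note effect, scanned with 50 ms windows.
cohort:
  nParticipants: 8
  trialsPerGroup: 10
  regions: [R01, R02, R03, R04, R05, R06]
  epoch: [0, 400]
  binMs: 5
  pCredibleLong: 0.536
  pCredibleShort: 0.409
  plantedEffects:
    - casePair: [LT, LF]
      regions: [R02, R05]
      window: [150, 250]
      amplitude: 1.5
      elevated: LT
scan:
  epoch: [0, 400]
  binMs: 5
  lengths: [50]
  maxRegions: 3
pair: long
nTrain: 6
nValidation: 2
B: 25
seed: 42
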
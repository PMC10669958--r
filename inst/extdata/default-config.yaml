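# Demonstration-scale end-to-end run: small phantoms, a tiny network and a
# short training schedule so the whole chain executes in well under a minute.
pipeline:
  marginMm: 2
  targetSpacingMm: 0.5
  inputShape: [32, 32, 32]
  minLesionVolumeCm3: 0.001
  dilationRadiusVoxels: 1
  connectivity: 26
  probCutoff: 0.5
  resizeMode: interpolate
network:
  nLevels: 3
  baseChannels: 2
  leakySlope: 0.01
  deepSupervision: true
  attentionGates: true
  learningRate: 0.001
  batchSize: 2
phantom:
  gridShape: [48, 48, 36]
  spacingMm: 0.4
  nTeeth: 2
  crownSemiAxesMm: [3.2, 2.8, 2.8]
  rootSemiAxesMm: [4.5, 2.0, 2.0]
  crownExponent: 4
  noiseSigma: 0.05
run:
  trainSamples: 3
  testSamples: 1
  steps: 20
  lesionPrevalence: 0.5
  lesionVolumeRangeMm3: [10, 25]
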
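# Example pipeline configuration: simulate a small two-cycle trial and fit
# GBLUP and GOBLUP-MI for grain yield and wort colour.
simulate:
  nLines: 60
  nSnps: 300
  nCycles: 2
  locations: [LocA]
  trialsPerEnv: 1
  plotsGrid: [6, 8]
  nMiFeatures: 100
  seed: 8
traits: [GY, WC]
models: [GBLUP, GOBLUP-MI]
mafMin: 0.05
callrateMin: 0.90
savgolWindow: 11
savgolPolyorder: 2
pcaVarTarget: 0.99
gxeDiagWeight: dG
cv:
  run: false
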
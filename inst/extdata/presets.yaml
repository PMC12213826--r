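# Incumbent configurations per imaging regime: encoder subset, neighbourhood
# bounds, entropy threshold, retrieval metric, vote reweighting. The
# lisc-transfer and cell-death-lionheart-transfer entries reuse the source
# regime's search parameters where none were tuned separately; the fallback
# preset is the recommended starting combination for unseen data.
wbc:
  encoders: [SAM, ConvNeXT, SWIN, CLIP]
  k_min: 3
  k_max: 1000
  entropy_threshold: 0.3
  metric: L2
  reweight: true
lisc-transfer:
  encoders: [DINO, ConvNeXT, SWIN, ViTMAE]
  k_min: 3
  k_max: 1000
  entropy_threshold: 0.3
  metric: L2
  reweight: true
cell-death-nanolive:
  encoders: [SAM, ConvNeXT, SWIN, CLIP, ViTMAE]
  k_min: 3
  k_max: 100
  entropy_threshold: 0.6
  metric: Canberra
  reweight: true
cell-death-lionheart-transfer:
  encoders: [SAM, DINO, SWIN]
  k_min: 10
  k_max: 1000
  entropy_threshold: 0.1
  metric: L2
  reweight: true
cell-type:
  encoders: [SAM, DINO, ConvNeXT, CLIP]
  k_min: 20
  k_max: 1000
  entropy_threshold: 0.2
  metric: L2
  reweight: true
pbmc-mixtures:
  encoders: [SAM, DINO, ConvNeXT, SWIN, CLIP]
  k_min: 33
  k_max: 1000
  entropy_threshold: 0.2
  metric: L2
  reweight: false
dino-convnext-swin:
  encoders: [DINO, ConvNeXT, SWIN]
  k_min: 3
  k_max: 1000
  entropy_threshold: 0.3
  metric: L2
  reweight: true
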
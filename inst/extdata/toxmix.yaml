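name: ToxMix
full_strength_total: 100
components:
- component: Retene
  proportion_percent: 68.6
  tef: 0.001
- component: Benzo[a]fluorene
  proportion_percent: 16.8
  tef: 0.001
- component: Benzo[b]fluorene
  proportion_percent: 8.42
  tef: 0.001
- component: Benzo[c]fluorene
  proportion_percent: 4.21
  tef: 0.001
- component: Triphenylene
  proportion_percent: 1.68
  tef: 0.001
- component: Benzo[e]pyrene
  proportion_percent: 0.168
  tef: 1
- component: Benzo[ghi]perylene
  proportion_percent: 0.0842
  tef: 0.01
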
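name: AbundMix
full_strength_total: 100
components:
- component: Naphthalene
  proportion_percent: 44
- component: Acenaphthene
  proportion_percent: 18.3
- component: 2-methylnaphthalene
  proportion_percent: 15.9
- component: 1-methylnaphthalene
  proportion_percent: 11.9
- component: Fluorene
  proportion_percent: 6.7
- component: Phenanthrene
  proportion_percent: 3.16
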
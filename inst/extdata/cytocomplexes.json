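[
  {"name": "pseudothummi", "combination": "AE CD BF G"},
  {"name": "thummi", "combination": "AB CD EF G"},
  {"name": "parathummi", "combination": "AC BF DE G"}
]
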
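[
  {
    "name": "pigST_A",
    "arm": "A",
    "scope": "cosmopolitan_basic",
    "formula": "1-19",
    "reference": ["1", "2", "3", "4", "5", "6", "7", "8", "9", "10", "11", "12", "13", "14", "15", "16", "17", "18", "19"]
  },
  {
    "name": "pigST_C",
    "arm": "C",
    "scope": "reference_standard",
    "formula": "1a-21",
    "reference": ["1a", "1b", "2", "3", "4", "5", "6", "7", "8", "9", "10", "11", "12", "13", "14", "15", "16", "17", "18", "19", "20", "21"]
  },
  {
    "name": "pigST_D",
    "arm": "D",
    "scope": "reference_standard",
    "formula": "1-18",
    "reference": ["1", "2", "3", "4", "5", "6", "7", "8", "9", "10", "11", "12", "13", "14", "15", "16", "17", "18"]
  },
  {
    "name": "pigST_E",
    "arm": "E",
    "scope": "cosmopolitan_basic",
    "formula": "1-17",
    "reference": ["1", "2", "3", "4", "5", "6", "7", "8", "9", "10", "11", "12", "13a", "13b", "14", "15", "16", "17"]
  },
  {
    "name": "pigST_F",
    "arm": "F",
    "scope": "cosmopolitan_basic",
    "formula": "1-20",
    "reference": ["1", "2", "3", "4", "5", "6", "7", "8", "9", "10", "11", "12", "13", "14", "15", "16", "17", "18", "19", "20"]
  },
  {
    "name": "holA1",
    "arm": "A",
    "scope": "cosmopolitan_basic",
    "formula": "1-19",
    "reference": ["1", "2", "3", "4", "5", "6", "7", "8", "9", "10", "11", "12", "13", "14", "15", "16", "17", "18", "19"]
  },
  {
    "name": "lonC1",
    "arm": "C",
    "scope": "cosmopolitan_basic",
    "formula": "1a-1b 13 7-2 12-8 14-15 21-16",
    "reference": ["1a", "1b", "2", "3", "4", "5", "6", "7", "8", "9", "10", "11", "12", "13", "14", "15", "16", "17", "18", "19", "20", "21"]
  },
  {
    "name": "lonE1",
    "arm": "E",
    "scope": "cosmopolitan_basic",
    "formula": "13b-8 14 1-7 15-17",
    "reference": ["1", "2", "3", "4", "5", "6", "7", "8", "9", "10", "11", "12", "13a", "13b", "14", "15", "16", "17"]
  },
  {
    "name": "aciE1",
    "arm": "E",
    "scope": "cosmopolitan_basic",
    "formula": "1-7 12-8 13a-17",
    "reference": ["1", "2", "3", "4", "5", "6", "7", "8", "9", "10", "11", "12", "13a", "13b", "14", "15", "16", "17"]
  },
  {
    "name": "aprE1",
    "arm": "E",
    "scope": "cosmopolitan_basic",
    "formula": "1-2 13a-10 6-9 5-3 13b-17",
    "reference": ["1", "2", "3", "4", "5", "6", "7", "8", "9", "10", "11", "12", "13a", "13b", "14", "15", "16", "17"]
  },
  {
    "name": "pluE_stub",
    "arm": "E",
    "scope": "cosmopolitan_basic",
    "formula": null,
    "reference": []
  },
  {
    "name": "saxE_stub",
    "arm": "E",
    "scope": "cosmopolitan_basic",
    "formula": null,
    "reference": []
  }
]
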
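{
  "species": "Chironomus formosipennis",
  "haploid_n": 4,
  "arm_combination": "AB CD EF G",
  "references": {
    "A": ["1", "2", "3", "4", "5", "6", "7", "8", "9", "10", "11", "12", "13", "14", "15", "16", "17", "18", "19"],
    "B": ["1", "2", "3", "4", "5", "6", "7", "8", "9", "10", "11", "12", "13", "14", "15"],
    "C": ["1a", "1b", "2", "3", "4", "5", "6", "7", "8", "9", "10", "11", "12", "13", "14", "15", "16", "17", "18", "19", "20", "21"],
    "D": ["1", "2", "3", "4", "5", "6", "7", "8", "9", "10", "11", "12", "13", "14", "15", "16", "17", "18"],
    "E": ["1", "2", "3", "4", "5", "6", "7", "8", "9", "10", "11", "12", "13a", "13b", "14", "15", "16", "17"],
    "F": ["1", "2", "3", "4", "5", "6", "7", "8", "9", "10", "11", "12", "13", "14", "15", "16", "17", "18", "19", "20"],
    "G": ["1", "2", "3", "4", "5", "6", "7", "8", "9", "10", "11", "12"]
  },
  "arms": {
    "A": [],
    "B": [],
    "C": [],
    "D": [],
    "E": [
      {
        "code": "frmE1",
        "formula": "1-2 13a-10 6-9 5-3 13b-17",
        "annotations": []
      }
    ],
    "F": [],
    "G": []
  },
  "notes": "Transcribed from the species description; band formulas are SYNTHETIC placeholders (photomap formulas are not machine-readable), constructed to satisfy the stated identities and derivations. Only arm E could be mapped."
}
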
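{
  "species": "Chironomus sp. Nakuru",
  "haploid_n": 4,
  "arm_combination": "AE CD BF G",
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
    "A": [
      {
        "code": "nakA1",
        "formula": "1-19",
        "annotations": []
      }
    ],
    "B": [],
    "C": [
      {
        "code": "nakC1",
        "formula": "1a 4-2 7 13 1b 5-6 12-8 14-15 21-16",
        "annotations": []
      }
    ],
    "D": [
      {
        "code": "nakD1",
        "formula": "1 12-8 2-3 13 7-4 14-18",
        "annotations": []
      }
    ],
    "E": [
      {
        "code": "nakE1",
        "formula": "2-1 4-3 13b-8 14 5-7 15-17",
        "annotations": []
      }
    ],
    "F": [
      {
        "code": "nakF1",
        "formula": "1 13-12 10-7 11 5-6 4-2 14-20",
        "annotations": [
          {
            "feature": "nucleolus",
            "position": "17-19"
          }
        ]
      }
    ],
    "G": [
      {
        "code": "nakG1",
        "formula": null,
        "annotations": []
      }
    ]
  },
  "notes": "Transcribed from the species description; band formulas are SYNTHETIC placeholders (photomap formulas are not machine-readable), constructed to satisfy the stated identities and derivations."
}
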
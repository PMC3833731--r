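{
  "species": "Chironomus alluaudi",
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
        "code": "allA1",
        "formula": "1-19",
        "annotations": []
      }
    ],
    "B": [],
    "C": [
      {
        "code": "allC1",
        "formula": "1a-2 12-13 3 7-8 16-14 19-21 17 9 18 4-6 11-10",
        "annotations": []
      },
      {
        "code": "allC2",
        "formula": "1a-2 12-13 3 7-8 20-19 14-16 21 17 9 18 4-6 11-10",
        "annotations": []
      }
    ],
    "D": [
      {
        "code": "allD1",
        "formula": "1-5 14-6 15-18",
        "annotations": []
      }
    ],
    "E": [
      {
        "code": "allE1",
        "formula": "1-17",
        "annotations": []
      }
    ],
    "F": [
      {
        "code": "allF1",
        "formula": "1-20",
        "annotations": []
      }
    ],
    "G": [
      {
        "code": "allG1",
        "formula": null,
        "annotations": []
      },
      {
        "code": "allG2",
        "formula": null,
        "annotations": []
      }
    ]
  },
  "notes": "Transcribed from the species description; band formulas are SYNTHETIC placeholders (photomap formulas are not machine-readable), constructed to satisfy the stated identities and derivations."
}
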
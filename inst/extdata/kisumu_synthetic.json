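{
  "species": "Chironomus sp. Kisumu",
  "haploid_n": 4,
  "arm_combination": "AC BF DE G",
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
        "code": "kisA1",
        "formula": "1-2 11 18-15 9-10 3-8 14-12 19",
        "annotations": []
      }
    ],
    "B": [
      {
        "code": "kisB1",
        "formula": null,
        "annotations": []
      }
    ],
    "C": [
      {
        "code": "kisC1",
        "formula": "1a 9-8 11-17 5-4 19-18 10 21 7 6 2-3 20 1b",
        "annotations": []
      }
    ],
    "D": [
      {
        "code": "kisD1",
        "formula": "1 4-2 5 16 14-13 15 12-10 8 7 9 6 17-18",
        "annotations": []
      }
    ],
    "E": [
      {
        "code": "kisE1",
        "formula": "1-5 8-6 9 13b-10 14-17",
        "annotations": [
          {
            "feature": "nucleolus",
            "position": "13a"
          }
        ]
      }
    ],
    "F": [
      {
        "code": "kisF1",
        "formula": null,
        "annotations": []
      }
    ],
    "G": []
  },
  "notes": "Transcribed from the species description; band formulas are SYNTHETIC placeholders (photomap formulas are not machine-readable), constructed to satisfy the stated identities and derivations."
}
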
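{
  "species": "Chironomus transvaalensis",
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
        "code": "trvA1",
        "formula": "1-2 8-3 9-19",
        "annotations": []
      }
    ],
    "B": [],
    "C": [
      {
        "code": "trvC1",
        "formula": "1a-1b 13 7 14 12-9 15 21-18 5-6 8 2-4 17-16",
        "annotations": []
      },
      {
        "code": "trvC2",
        "formula": "1a-1b 13 7 14 12-9 15 6-5 18-21 8 2-4 17-16",
        "annotations": []
      }
    ],
    "D": [
      {
        "code": "trvD1",
        "formula": "1 13-11 3-2 14-17 7-4 10 18 8-9",
        "annotations": []
      }
    ],
    "E": [
      {
        "code": "trvE1",
        "formula": "1-2 7-3 12-8 13a-17",
        "annotations": []
      }
    ],
    "F": [
      {
        "code": "trvF1",
        "formula": "1-6 19-18 11-7 12-17 20",
        "annotations": []
      }
    ],
    "G": [
      {
        "code": "trvG1",
        "formula": null,
        "annotations": []
      },
      {
        "code": "trvG2",
        "formula": null,
        "annotations": []
      },
      {
        "code": "trvG3",
        "formula": null,
        "annotations": []
      }
    ]
  },
  "notes": "Transcribed from the species description; band formulas are SYNTHETIC placeholders (photomap formulas are not machine-readable), constructed to satisfy the stated identities and derivations."
}
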
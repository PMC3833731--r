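{
  "species": "Chironomus prope pulcher",
  "haploid_n": 3,
  "arm_combination": "AB CD FEG",
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
        "code": "pulA1",
        "formula": "1-3 17-16 18 12-9 13 4-8 14-15 19",
        "annotations": []
      }
    ],
    "B": [
      {
        "code": "pulB1",
        "formula": null,
        "annotations": []
      }
    ],
    "C": [
      {
        "code": "pulC1",
        "formula": null,
        "annotations": []
      },
      {
        "code": "pulC2",
        "formula": null,
        "annotations": []
      }
    ],
    "D": [
      {
        "code": "pulD1",
        "formula": "1-3 11-16 6 10-9 7 17 5-4 8 18",
        "annotations": []
      }
    ],
    "E": [
      {
        "code": "pulE1",
        "formula": "8-6 12-16 3-1 9-11 5-4 17",
        "annotations": []
      }
    ],
    "F": [
      {
        "code": "pulF1",
        "formula": "1-6 19-7 20",
        "annotations": [
          {
            "feature": "nucleolus",
            "position": "20"
          }
        ]
      }
    ],
    "G": []
  },
  "notes": "Transcribed from the species description; band formulas are SYNTHETIC placeholders (photomap formulas are not machine-readable), constructed to satisfy the stated identities and derivations."
}
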
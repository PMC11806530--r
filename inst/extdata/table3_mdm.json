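{
  "_notes": "Hand-curated transcription of the published relationship tables for the pediatric-medication MDM instance.  The level-1 aggregate rows/columns of the source table are omitted: the influence matrix is restricted to the 17 level-2 factors.  Several run-together numerals in the source are typographically ambiguous; the interpretation used for each such cell is flagged in '_ambiguous_cells'.  The elicited TF x MF scores are printed without column labels in the source; the column-order fill encoded here (A: time=1, effect=5, safety=9; B: time=3, flexibility=6, effect=7, safety=8; C: effect=2, flexibility=4) reproduces the narrative ordering of the elicited priorities.  af_mf_printed is the published AF x MF block, already scaled so each column's reference factor equals 1.",
  "_ambiguous_cells": [
    {
      "cell": "af_af[A-3.2, B-2.3]",
      "value": 2,
      "note": "run-together digits; could also be read as an entry for the level-1 feedback aggregate"
    },
    {
      "cell": "af_af[*, C-1.2]",
      "value": "0.020-0.139",
      "note": "trailing small entries could alternatively attach to the level-1 post-medication aggregates"
    },
    {
      "cell": "tf_mf[A, time]",
      "value": 1,
      "note": "unlabeled '1' in the source row; assigned to the time column by column-order convention"
    }
  ],
  "factors": [
    {
      "id": "A-1.1",
      "label": "Common diseases"
    },
    {
      "id": "A-1.2",
      "label": "Disease severity"
    },
    {
      "id": "A-2.1",
      "label": "Childhood status"
    },
    {
      "id": "A-2.2",
      "label": "Parental cognition"
    },
    {
      "id": "A-3.1",
      "label": "Hospital infrastructure"
    },
    {
      "id": "A-3.2",
      "label": "Doctor's literacy"
    },
    {
      "id": "A-3.3",
      "label": "Doctor preferences"
    },
    {
      "id": "B-1.1",
      "label": "Timeliness of medication"
    },
    {
      "id": "B-1.2",
      "label": "Drug control degree"
    },
    {
      "id": "B-2.1",
      "label": "Improvement rate of children"
    },
    {
      "id": "B-2.2",
      "label": "Child medication acceptance"
    },
    {
      "id": "B-2.3",
      "label": "Disease variability"
    },
    {
      "id": "B-2.4",
      "label": "External environment"
    },
    {
      "id": "C-1.1",
      "label": "Health records"
    },
    {
      "id": "C-1.2",
      "label": "Medication tracking"
    },
    {
      "id": "C-2.1",
      "label": "Health habits"
    },
    {
      "id": "C-2.2",
      "label": "Medical network"
    }
  ],
  "mf_weights": {
    "time": 0.15,
    "price": 0.1,
    "effect": 0.3,
    "flexibility": 0.05,
    "safety": 0.4
  },
  "tf_mf": {
    "rows": ["A", "B", "C"],
    "cols": ["time", "price", "effect", "flexibility", "safety"],
    "values": [
      [1, 0, 5, 0, 9],
      [3, 0, 7, 6, 8],
      [0, 0, 2, 4, 0]
    ]
  },
  "af_tf": {
    "rows": ["A-1.1", "A-1.2", "A-2.1", "A-2.2", "A-3.1", "A-3.2", "A-3.3", "B-1.1", "B-1.2", "B-2.1", "B-2.2", "B-2.3", "B-2.4", "C-1.1", "C-1.2", "C-2.1", "C-2.2"],
    "cols": ["A", "B", "C"],
    "values": [
      [0.244, 0.07, 0.023],
      [0.367, 0.116, 0.038],
      [0.713, 0.308, 0.053],
      [0.509, 1, 0.429],
      [0.167, 0.488, 0.371],
      [1, 0.837, 0.182],
      [0.667, 0, 0],
      [0, 0.598, 0],
      [0, 0.498, 0],
      [0, 0.697, 0.114],
      [0, 0.976, 0.159],
      [0, 0.558, 0.091],
      [0.122, 0.349, 0.068],
      [0, 0.488, 0.582],
      [0.333, 0, 0.339],
      [0.255, 0.701, 0.857],
      [0, 0, 0.857]
    ]
  },
  "af_af": {
    "rows": ["A-1.1", "A-1.2", "A-2.1", "A-2.2", "A-3.1", "A-3.2", "A-3.3", "B-1.1", "B-1.2", "B-2.1", "B-2.2", "B-2.3", "B-2.4", "C-1.1", "C-1.2", "C-2.1", "C-2.2"],
    "cols": ["A-1.1", "A-1.2", "A-2.1", "A-2.2", "A-3.1", "A-3.2", "A-3.3", "B-1.1", "B-1.2", "B-2.1", "B-2.2", "B-2.3", "B-2.4", "C-1.1", "C-1.2", "C-2.1", "C-2.2"],
    "values": [
      [0, 0, 0, 0, 0, 0, 0, 0, 0, 0.4, 0, 0, 0, 0, 0.02, 0, 0],
      [0, 0, 0, 0, 0, 0, 0, 0, 0, 0.667, 0, 0, 0, 0, 0.033, 0, 0],
      [0, 0, 0, 0, 0, 0, 0, 0, 0, 0.933, 0, 0, 0, 0, 0.046, 0, 0],
      [0, 0, 0, 0, 0, 0, 0, 2, 0, 0, 0, 0, 0, 0, 0, 0, 2],
      [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 0, 2, 0, 0, 0],
      [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 2, 0, 0, 0, 0, 0],
      [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0],
      [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0],
      [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0],
      [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0.099, 0, 0],
      [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0.139, 0, 0],
      [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0.08, 0, 0],
      [0, 0, 0, 0, 0, 0, 0, 0, 0, 0.2, 0, 0, 0, 0, 0.06, 0, 0],
      [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 2, 0, 0, 0, 0, 0, 0],
      [0, 0, 0, 0, 0, 0, 2, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0],
      [0, 0, 0, 2, 0, 0, 0, 1, 0, 0, 0, 0, 0, 0, 0, 0, 1],
      [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0]
    ]
  },
  "af_mf_printed": {
    "rows": ["A-1.1", "A-1.2", "A-2.1", "A-2.2", "A-3.1", "A-3.2", "A-3.3", "B-1.1", "B-1.2", "B-2.1", "B-2.2", "B-2.3", "B-2.4", "C-1.1", "C-1.2", "C-2.1", "C-2.2"],
    "cols": ["time", "price", "effect", "flexibility", "safety"],
    "values": [
      [0.07, 0.343, 0.262, 0.067, 0.176],
      [0.116, 0.514, 0.335, 0.111, 0.27],
      [0.308, 1, 1, 0.27, 0.566],
      [1, 0.714, 0, 1.01, 0.802],
      [0.488, 0.234, 1.078, 0.578, 0.344],
      [0.837, 1.403, 0.32, 0.753, 1],
      [0, 0.935, 0, 0, 0.382],
      [0.598, 0, 0.335, 0.469, 0.305],
      [0.498, 0, 0.192, 0.391, 0.254],
      [0.697, 0, 0.687, 0.607, 0.355],
      [0.976, 0, 0.393, 0.85, 0.498],
      [0.558, 0, 0.306, 0.486, 0.284],
      [0.349, 0.171, 0, 0.31, 0.248],
      [0.488, 0, 0.225, 0.688, 0.249],
      [0, 0.468, 0, 0.177, 0.191],
      [0.701, 0.357, 0.165, 1, 0.504],
      [0, 0, 0, 0.449, 0]
    ]
  }
}
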
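{
  "format_version": "1.0",
  "schema": {
    "csr_spans": [
      {
        "csr": 1,
        "start": 1,
        "end": 5
      },
      {
        "csr": 2,
        "start": 6,
        "end": 11
      },
      {
        "csr": 3,
        "start": 12,
        "end": 17
      },
      {
        "csr": 4,
        "start": 18,
        "end": 27
      },
      {
        "csr": 5,
        "start": 28,
        "end": 36
      }
    ],
    "nucleophile_pos": 15,
    "donor_pos": 20,
    "diagnostic_positions": [1, 12, 23, 35, 36],
    "version": "1.0"
  },
  "catalogue": [
    {
      "group": "AAMY",
      "kind": "enzyme",
      "n": 154,
      "n_archaea": 99,
      "n_bacteria": 55,
      "n_characterized": 1,
      "mean_length": 414
    },
    {
      "group": "AAMY-like",
      "kind": "like",
      "partner": "AAMY",
      "n": 126,
      "n_archaea": 60,
      "n_bacteria": 66,
      "n_characterized": 0,
      "mean_length": 443
    },
    {
      "group": "4AGT",
      "kind": "enzyme",
      "n": 107,
      "n_archaea": 38,
      "n_bacteria": 69,
      "n_characterized": 5,
      "mean_length": 670
    },
    {
      "group": "4AGT-like",
      "kind": "like",
      "partner": "4AGT",
      "n": 63,
      "n_archaea": 0,
      "n_bacteria": 63,
      "n_characterized": 0,
      "mean_length": 623
    },
    {
      "group": "APU",
      "kind": "enzyme",
      "n": 268,
      "n_archaea": 74,
      "n_bacteria": 194,
      "n_characterized": 8,
      "mean_length": 814
    },
    {
      "group": "APU-CMD",
      "kind": "enzyme",
      "n": 40,
      "n_archaea": 20,
      "n_bacteria": 20,
      "n_characterized": 4,
      "mean_length": 529
    },
    {
      "group": "APU-CMD-like",
      "kind": "like",
      "partner": "APU-CMD",
      "n": 5,
      "n_archaea": 0,
      "n_bacteria": 5,
      "n_characterized": 0,
      "mean_length": 728
    },
    {
      "group": "MGA",
      "kind": "enzyme",
      "n": 34,
      "n_archaea": 34,
      "n_bacteria": 0,
      "n_characterized": 3,
      "mean_length": 590
    },
    {
      "group": "MGA-like",
      "kind": "like",
      "partner": "MGA",
      "n": 1,
      "n_archaea": 0,
      "n_bacteria": 1,
      "n_characterized": 0,
      "mean_length": 479
    },
    {
      "group": "AGAL",
      "kind": "enzyme",
      "n": 14,
      "n_archaea": 14,
      "n_bacteria": 0,
      "n_characterized": 1,
      "mean_length": 362
    },
    {
      "group": "AGAL-related",
      "kind": "enzyme",
      "n": 15,
      "n_archaea": 0,
      "n_bacteria": 15,
      "n_characterized": 0,
      "mean_length": 660
    },
    {
      "group": "NSA",
      "kind": "enzyme",
      "n": 170,
      "n_archaea": 18,
      "n_bacteria": 152,
      "n_characterized": 1,
      "mean_length": 785
    },
    {
      "group": "GBE",
      "kind": "enzyme",
      "n": 545,
      "n_archaea": 26,
      "n_bacteria": 519,
      "n_characterized": 4,
      "mean_length": 546
    },
    {
      "group": "GBE-like",
      "kind": "like",
      "partner": "GBE",
      "n": 60,
      "n_archaea": 0,
      "n_bacteria": 60,
      "n_characterized": 0,
      "mean_length": 520
    }
  ],
  "rules": {
    "AAMY": {
      "p1": ["E", "Q"],
      "p12": ["R", "E"],
      "p23": "T",
      "p35": "Y",
      "p36": "Y"
    },
    "NSA": {
      "p1": null,
      "p12": ["W", "F", "Y", "H"],
      "p23": "S",
      "p35": "F",
      "p36": "F"
    },
    "MGA": {
      "p1": null,
      "p12": ["W", "F", "Y", "H"],
      "p23": "A",
      "p35": "F",
      "p36": "W"
    },
    "4AGT": {
      "p1": null,
      "p12": ["W", "F", "Y", "H"],
      "p23": "K",
      "p35": null,
      "p36": null
    },
    "APU": {
      "p1": null,
      "p12": ["W", "F", "Y", "H"],
      "p23": null,
      "p35": "W",
      "p36": "W"
    },
    "APU-CMD": {
      "p1": null,
      "p12": ["W", "F", "Y", "H"],
      "p23": null,
      "p35": null,
      "p36": null
    },
    "GBE": {
      "p1": null,
      "p12": ["W", "F", "Y", "H"],
      "p23": "L",
      "p35": "F",
      "p36": ["A", "C", "D", "E", "G", "I", "K", "L", "M", "N", "P", "Q", "R", "S", "T", "V"]
    },
    "AGAL": {
      "p1": null,
      "p12": ["W", "F", "Y", "H"],
      "p23": "F",
      "p35": "G",
      "p36": "W"
    },
    "AGAL-related": {
      "p1": null,
      "p12": ["W", "F", "Y", "H"],
      "p23": "F",
      "p35": "T",
      "p36": ["K", "H"]
    }
  }
}
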
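{
  "_notes": "Published global importance column (AF x PD) of the pediatric medication MDM instance; authoritative input for the stage and first-level aggregation arithmetic.  The printed entries sum to 1.001 due to rounding in the source.",
  "weights": {
    "A-1.1": 0.031,
    "A-1.2": 0.045,
    "A-2.1": 0.108,
    "A-2.2": 0.094,
    "A-3.1": 0.093,
    "A-3.2": 0.126,
    "A-3.3": 0.039,
    "B-1.1": 0.053,
    "B-1.2": 0.04,
    "B-2.1": 0.076,
    "B-2.2": 0.08,
    "B-2.3": 0.049,
    "B-2.4": 0.029,
    "C-1.1": 0.043,
    "C-1.2": 0.021,
    "C-2.1": 0.07,
    "C-2.2": 0.004
  }
}
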
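[
  {
    "type": "I",
    "comment": "inter-strand; surface a = helices H1/H4, surface b = H2/H3",
    "surface_a": [441, 444, 445, 448, 489, 492, 495],
    "surface_b": [457, 461, 467, 471],
    "pairs": [[444, 461], [448, 457]]
  },
  {
    "type": "II",
    "comment": "inter-strand; surface a = C-terminal end of H4 with H4-H5 and H2-H3 loops, surface b = H1-H2 loop, N-terminus of H2 and the visible C-terminal segment",
    "surface_a": [470, 497],
    "surface_b": [450, 452, 453, 455, 458, 512, 514],
    "pairs": [[470, 455], [512, 458], [497, 450], [497, 452], [497, 514]]
  },
  {
    "type": "III",
    "comment": "intra-strand along the helical strand; surface a = H3, surface b = H3-H4 loop and N-terminus of H4",
    "surface_a": [472, 475, 481, 482],
    "surface_b": [476, 483, 488],
    "pairs": [[472, 488], [475, 483]]
  }
]
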
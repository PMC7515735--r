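{
  "version": 1,
  "comment": "Initial Hoogsteen-type (H) and reverse-Hoogsteen-type (RH) hydrogen-bond templates for each third-strand/duplex-purine triad, plus named variant patterns seen to replace them in stable trajectories. 'third' and 'duplex' are heavy-atom names; 'duplex_base' says which duplex base carries the atom (purine unless stated); 'donor' says which side donates.",
  "triads": {
    "C+.G": {
      "H": [
        {"third": "N3", "duplex": "N7", "duplex_base": "purine", "donor": "third"},
        {"third": "N4", "duplex": "O6", "duplex_base": "purine", "donor": "third"}
      ],
      "RH": [
        {"third": "N3", "duplex": "O6", "duplex_base": "purine", "donor": "third"},
        {"third": "N4", "duplex": "N7", "duplex_base": "purine", "donor": "third"}
      ]
    },
    "T.A": {
      "H": [
        {"third": "N3", "duplex": "N7", "duplex_base": "purine", "donor": "third"},
        {"third": "O4", "duplex": "N6", "duplex_base": "purine", "donor": "duplex"}
      ],
      "RH": [
        {"third": "N3", "duplex": "N7", "duplex_base": "purine", "donor": "third"},
        {"third": "O2", "duplex": "N6", "duplex_base": "purine", "donor": "duplex"}
      ]
    },
    "G.G": {
      "H": [
        {"third": "N1", "duplex": "O6", "duplex_base": "purine", "donor": "third"},
        {"third": "N2", "duplex": "N7", "duplex_base": "purine", "donor": "third"}
      ],
      "RH": [
        {"third": "N1", "duplex": "N7", "duplex_base": "purine", "donor": "third"},
        {"third": "N2", "duplex": "O6", "duplex_base": "purine", "donor": "third"}
      ]
    },
    "A.G": {
      "H": [
        {"third": "N6", "duplex": "O6", "duplex_base": "purine", "donor": "third"}
      ],
      "RH": [
        {"third": "N6", "duplex": "N7", "duplex_base": "purine", "donor": "third"}
      ]
    },
    "A+.G": {
      "H": [
        {"third": "N1", "duplex": "N7", "duplex_base": "purine", "donor": "third"},
        {"third": "N6", "duplex": "O6", "duplex_base": "purine", "donor": "third"}
      ],
      "RH": [
        {"third": "N1", "duplex": "O6", "duplex_base": "purine", "donor": "third"},
        {"third": "N6", "duplex": "N7", "duplex_base": "purine", "donor": "third"}
      ]
    },
    "A.A": {
      "H": [
        {"third": "N6", "duplex": "N7", "duplex_base": "purine", "donor": "third"},
        {"third": "N7", "duplex": "N6", "duplex_base": "purine", "donor": "duplex"}
      ],
      "RH": [
        {"third": "N6", "duplex": "N7", "duplex_base": "purine", "donor": "third"},
        {"third": "N7", "duplex": "N6", "duplex_base": "purine", "donor": "duplex"}
      ]
    },
    "G.A": {
      "H": [
        {"third": "N1", "duplex": "N7", "duplex_base": "purine", "donor": "third"}
      ],
      "RH": [
        {"third": "O6", "duplex": "N6", "duplex_base": "purine", "donor": "duplex"}
      ]
    }
  },
  "variants": {
    "G.G": [
      {"name": "bifurcated-N1N2-O6",
       "bonds": [
         {"third": "N1", "duplex": "O6", "duplex_base": "purine", "donor": "third"},
         {"third": "N2", "duplex": "O6", "duplex_base": "purine", "donor": "third"}
       ]},
      {"name": "O6-N4(C)+N1-O6",
       "bonds": [
         {"third": "O6", "duplex": "N4", "duplex_base": "pyrimidine", "donor": "duplex"},
         {"third": "N1", "duplex": "O6", "duplex_base": "purine", "donor": "third"}
       ]},
      {"name": "bifurcated-N1N2-N7",
       "bonds": [
         {"third": "N1", "duplex": "N7", "duplex_base": "purine", "donor": "third"},
         {"third": "N2", "duplex": "N7", "duplex_base": "purine", "donor": "third"}
       ]}
    ],
    "A.A": [
      {"name": "duplex-crossing-N6-O4+N1-N6",
       "bonds": [
         {"third": "N6", "duplex": "O4", "duplex_base": "pyrimidine", "donor": "third"},
         {"third": "N1", "duplex": "N6", "duplex_base": "purine", "donor": "duplex"}
       ]},
      {"name": "single-N6-O4",
       "bonds": [
         {"third": "N6", "duplex": "O4", "duplex_base": "pyrimidine", "donor": "third"}
       ]},
      {"name": "single-N1-N6",
       "bonds": [
         {"third": "N1", "duplex": "N6", "duplex_base": "purine", "donor": "duplex"}
       ]}
    ],
    "A+.G": [
      {"name": "N1-O6-isomer",
       "bonds": [
         {"third": "N1", "duplex": "O6", "duplex_base": "purine", "donor": "third"},
         {"third": "N6", "duplex": "O6", "duplex_base": "purine", "donor": "third"}
       ]},
      {"name": "single-N1-N7",
       "bonds": [
         {"third": "N1", "duplex": "N7", "duplex_base": "purine", "donor": "third"}
       ]},
      {"name": "single-N6-N7",
       "bonds": [
         {"third": "N6", "duplex": "N7", "duplex_base": "purine", "donor": "third"}
       ]}
    ],
    "G.A": [
      {"name": "bifurcated-N1N2-N7",
       "bonds": [
         {"third": "N1", "duplex": "N7", "duplex_base": "purine", "donor": "third"},
         {"third": "N2", "duplex": "N7", "duplex_base": "purine", "donor": "third"}
       ]},
      {"name": "O6-N6+N2-O4",
       "bonds": [
         {"third": "O6", "duplex": "N6", "duplex_base": "purine", "donor": "duplex"},
         {"third": "N2", "duplex": "O4", "duplex_base": "pyrimidine", "donor": "third"}
       ]}
    ]
  }
}
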
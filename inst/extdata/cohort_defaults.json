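{
  "n_networks": 57,
  "k": 7,
  "n_frames": 297,
  "tr": 2.0,
  "obs_noise_sd": 0.1,
  "base_noise": 0.05,
  "mean_dwell": {
    "AWAKE": 30,
    "PROP": 45,
    "SEVO": 60,
    "UWS": 50
  },
  "dwell_weights": {},
  "network_families": {
    "basal_ganglia": [
      1,
      5
    ],
    "auditory": [
      6,
      9
    ],
    "somatomotor": [
      10,
      19
    ],
    "visual": [
      20,
      29
    ],
    "default_mode": [
      30,
      39
    ],
    "attention": [
      40,
      49
    ],
    "cerebellar": [
      50,
      57
    ]
  },
  "pattern_blocks": {
    "1": {
      "description": "low overall correlation (conscious, AWAKE-specific)",
      "blocks": []
    },
    "2": {
      "description": "cortical synchrony anticorrelated with subcortex (propofol-specific)",
      "blocks": [
        {
          "families": [
            "auditory",
            "somatomotor",
            "visual",
            "default_mode",
            "attention"
          ],
          "r": 0.64
        },
        {
          "families": [
            "basal_ganglia",
            "cerebellar"
          ],
          "r": 0.2
        },
        {
          "families": [
            "auditory",
            "somatomotor",
            "visual",
            "default_mode",
            "attention"
          ],
          "families2": [
            "basal_ganglia",
            "cerebellar"
          ],
          "r": -0.36
        }
      ]
    },
    "3": {
      "description": "high correlation across sensory and motor systems (conscious)",
      "blocks": [
        {
          "families": [
            "auditory",
            "somatomotor",
            "visual"
          ],
          "r": 0.72
        }
      ]
    },
    "4": {
      "description": "subcortical-associative coupling, strong basal ganglia-cerebellar (UWS-dominant)",
      "blocks": [
        {
          "families": [
            "basal_ganglia",
            "cerebellar",
            "default_mode",
            "attention"
          ],
          "r": 0.35
        },
        {
          "families": [
            "basal_ganglia",
            "cerebellar"
          ],
          "r": 0.7
        }
      ]
    },
    "5": {
      "description": "default-mode/attention synchrony with visual coupling (shared AWAKE/PROP)",
      "blocks": [
        {
          "families": [
            "default_mode",
            "attention"
          ],
          "r": 0.65
        },
        {
          "families": [
            "visual"
          ],
          "r": 0.55
        }
      ]
    },
    "6": {
      "description": "sensorimotor-subcortical synchrony anticorrelated with associative cortex (UWS-specific)",
      "blocks": [
        {
          "families": [
            "basal_ganglia",
            "somatomotor",
            "cerebellar"
          ],
          "r": 0.64
        },
        {
          "families": [
            "default_mode",
            "attention"
          ],
          "r": 0.36
        },
        {
          "families": [
            "basal_ganglia",
            "somatomotor",
            "cerebellar"
          ],
          "families2": [
            "default_mode",
            "attention"
          ],
          "r": -0.48
        }
      ]
    },
    "7": {
      "description": "global hypersynchrony (deep anesthesia)",
      "blocks": [
        {
          "families": [
            "basal_ganglia",
            "auditory",
            "somatomotor",
            "visual",
            "default_mode",
            "attention",
            "cerebellar"
          ],
          "r": 0.35
        }
      ]
    }
  },
  "occupancy": {
    "AWAKE": {
      "1": 0.5,
      "3": 0.22,
      "5": 0.18,
      "4": 0.04,
      "7": 0.06
    },
    "PROP": {
      "1": 0.015,
      "3": 0.001,
      "2": 0.13,
      "7": 0.37,
      "5": 0.24,
      "4": 0.244
    },
    "SEVO": {
      "7": 0.99,
      "4": 0.005,
      "5": 0.005
    },
    "UWS": {
      "4": 0.6,
      "6": 0.26,
      "5": 0.07,
      "7": 0.07
    }
  },
  "forbidden_pairs": [
    [
      1,
      2
    ],
    [
      1,
      6
    ],
    [
      2,
      3
    ],
    [
      2,
      4
    ],
    [
      2,
      5
    ],
    [
      2,
      6
    ],
    [
      3,
      6
    ],
    [
      6,
      7
    ]
  ],
  "design": {
    "prop_pairs": 11,
    "sevo_pairs": 14,
    "controls": 20,
    "uws": 18
  },
  "activation": {
    "networks": [
      6,
      20,
      21,
      30,
      40,
      41
    ],
    "patterns": [
      1,
      3
    ],
    "shift": 0.5
  }
}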
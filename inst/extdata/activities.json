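[
  {
    "id": "gardening_light",
    "name": "Light gardening",
    "impact_ratings": {
      "shoulders": "mild",
      "arms": "mild",
      "column": "mild",
      "legs": "light",
      "feet": "light",
      "cognitive": "mild",
      "dangerous_tools": "hard"
    },
    "intensity_class": "low",
    "duration_min": 30
  },
  {
    "id": "arms_raise",
    "name": "Arms raise",
    "impact_ratings": {
      "shoulders": "light",
      "arms": "light",
      "cognitive": "light"
    },
    "intensity_class": "low",
    "duration_min": 10
  },
  {
    "id": "brisk_walk",
    "name": "Brisk walk",
    "impact_ratings": {
      "legs": "mild",
      "feet": "mild",
      "column": "light",
      "cognitive": "light"
    },
    "intensity_class": "high",
    "duration_min": 20
  },
  {
    "id": "chair_aerobics",
    "name": "Chair aerobics",
    "impact_ratings": {
      "shoulders": "light",
      "arms": "mild",
      "legs": "light",
      "cognitive": "light"
    },
    "intensity_class": "high",
    "duration_min": 15
  },
  {
    "id": "memory_cards",
    "name": "Memory card game",
    "impact_ratings": {
      "cognitive": "hard"
    },
    "intensity_class": "low",
    "duration_min": 25
  },
  {
    "id": "group_dance",
    "name": "Group dance session",
    "impact_ratings": {
      "shoulders": "mild",
      "arms": "mild",
      "column": "mild",
      "legs": "hard",
      "feet": "mild",
      "cognitive": "mild"
    },
    "intensity_class": "high",
    "duration_min": 40
  }
]
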
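{
  "entries": {
    "gold": [
      {
        "synset": ["gold"],
        "definition": "coins made of gold",
        "glosses": [],
        "hypernyms": [
          {
            "synset": ["precious metal"],
            "definition": "less common and valuable metals often used to make coins or jewelry"
          }
        ]
      },
      {
        "synset": ["amber", "gold"],
        "definition": "a deep yellow color",
        "glosses": ["an amber light illuminated the room"],
        "hypernyms": [
          {
            "synset": ["yellow", "yellowness"],
            "definition": "yellow color or pigment"
          }
        ]
      }
    ]
  },
  "morphology": {}
}
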
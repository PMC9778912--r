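{
  "PC_AA": {
    "saturation": {
      ":0": "C20-48:0",
      ":1": "C28-42:1",
      ":2": "C30-42:2",
      ":3": "C32-40:3",
      ":4": "C34-42:4",
      ":5": "C36-42:5",
      ":6": "C36-42:6"
    },
    "chain_length": {
      "30:X": "C30:0-2",
      "32:X": "C32:0-3",
      "34:X": "C34:1-4",
      "36:X": "C36:0-6",
      "38:X": "C38:0-6",
      "40:X": "C40:0-6",
      "42:X": "C42:0-6",
      "44:X": "C44:0"
    }
  },
  "PC_AE": {
    "saturation": {
      ":0": "C30-42:0",
      ":1": "C30-42:1",
      ":2": "C30-42:2",
      ":3": "C34-44:3",
      ":4": "C36-44:4",
      ":5": "C36-44:5",
      ":6": "C38-44:6"
    },
    "chain_length": {
      "30:X": "C30:0-2",
      "32:X": "C32:1-2",
      "34:X": "C34:0-3",
      "36:X": "C36:0-5",
      "38:X": "C38:0-6",
      "40:X": "C40:0-6",
      "42:X": "C42:0-5",
      "44:X": "C44:3-6"
    }
  }
}
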
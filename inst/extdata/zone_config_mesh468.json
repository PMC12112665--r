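{
  "mesh_size": 468,
  "left_eye": 33,
  "right_eye": 263,
  "zones": {
    "AU1":  {"name": "inner brow raiser", "indices": [8, 9, 107, 66, 336, 296, 168], "color": "green"},
    "AU4":  {"name": "brow lowerer",      "indices": [70, 63, 105, 300, 293, 334],   "color": "purple"},
    "AU6":  {"name": "cheek raiser",      "indices": [117, 118, 119, 346, 347, 348], "color": "blue"},
    "AU7":  {"name": "lid tightener",     "indices": [145, 153, 374, 380],           "color": "orange"},
    "AU9":  {"name": "nose wrinkler",     "indices": [48, 115, 220, 278, 344, 440],  "color": "black"},
    "AU10": {"name": "upper lip raiser",  "indices": [37, 0, 267, 39, 269],          "color": "brown"},
    "AU15": {"name": "lip corner depressor", "indices": [61, 76, 291, 306],          "color": "red"},
    "AU17": {"name": "chin raiser",       "indices": [152, 175, 199, 200, 428, 208], "color": "cyan"},
    "AU43": {"name": "eye closure",       "indices": [159, 158, 386, 385],           "color": "gray"},
    "AU44": {"name": "squint",            "indices": [7, 163, 144, 249, 390, 373],   "color": "yellow"}
  }
}
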
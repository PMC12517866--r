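{
  "n_survivors": 204,
  "table_atorvastatin": {
    "a": 4,
    "b": 29,
    "c": 13,
    "d": 158
  },
  "tto_atorvastatin": [7, 83],
  "demog_atorvastatin": {
    "total": 4,
    "female": 4,
    "male": 0,
    "unknown_sex": 0
  },
  "table_rosuvastatin": {
    "a": 4,
    "b": 33,
    "c": 13,
    "d": 154
  },
  "tto_rosuvastatin": [0, 44, 237],
  "demog_rosuvastatin": {
    "total": 4,
    "female": 1,
    "male": 3,
    "unknown_sex": 0
  }
}
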
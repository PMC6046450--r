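{
  "contaminants": ["CONTAM001", "CONTAM002", "CONTAM003", "CONTAM004", "CONTAM005", "CONTAM006"],
  "lambda": [0.74763620501913, 0.517205424668597, 0.618118362997046, 0.515360740841063, 0.761355102271541, 0.843079339578498, 0.879972851536291, 0.499873009571031, 0.889855176977399, 0.654636581895593, 0.801580775238882, 0.786909808705659, 0.591981293125648, 0.419725890868515, 0.613833432416106, 0.710597528554704, 0.728287760813139, 0.655205426800675, 0.610786224871949, 0.711926651967919, 0.574445334606857, 0.509427046785769, 0.78051592251684, 0.615517013768149],
  "retention": [0.492194263241452, 0.537732571776809, 0.685149781149792, 0.56490628944578, 0.646127854091773, 0.497343508227849, 0.589950546699745, 0.583616133849173, 0.558538056388611, 0.516723023923617, 0.656847731903972, 0.45347679913638, 0.563644467496792, 0.743327190648558, 0.594483979837351, 0.636206800600016, 0.549899386660869, 0.644961428844092, 0.619568595102695, 0.561594248628699, 0.724884533227539, 0.585662833588462, 0.668798686916942, 0.763703634839807],
  "birds": [
    {
      "bird_id": "B01_1",
      "origin": "N01",
      "treatment": "crossfostered",
      "rearing": "N01"
    },
    {
      "bird_id": "B01_2",
      "origin": "N01",
      "treatment": "crossfostered",
      "rearing": "N02"
    },
    {
      "bird_id": "B01_3",
      "origin": "N01",
      "treatment": "crossfostered",
      "rearing": "N01"
    },
    {
      "bird_id": "B01_4",
      "origin": "N01",
      "treatment": "crossfostered",
      "rearing": "N01"
    },
    {
      "bird_id": "B01_5",
      "origin": "N01",
      "treatment": "crossfostered",
      "rearing": "N02"
    },
    {
      "bird_id": "B01_6",
      "origin": "N01",
      "treatment": "crossfostered",
      "rearing": "N02"
    },
    {
      "bird_id": "B02_1",
      "origin": "N02",
      "treatment": "crossfostered",
      "rearing": "N02"
    },
    {
      "bird_id": "B02_2",
      "origin": "N02",
      "treatment": "crossfostered",
      "rearing": "N01"
    },
    {
      "bird_id": "B02_3",
      "origin": "N02",
      "treatment": "crossfostered",
      "rearing": "N02"
    },
    {
      "bird_id": "B02_4",
      "origin": "N02",
      "treatment": "crossfostered",
      "rearing": "N01"
    },
    {
      "bird_id": "B02_5",
      "origin": "N02",
      "treatment": "crossfostered",
      "rearing": "N02"
    },
    {
      "bird_id": "B02_6",
      "origin": "N02",
      "treatment": "crossfostered",
      "rearing": "N01"
    },
    {
      "bird_id": "B03_1",
      "origin": "N03",
      "treatment": "control",
      "rearing": "N03"
    },
    {
      "bird_id": "B03_2",
      "origin": "N03",
      "treatment": "control",
      "rearing": "N03"
    },
    {
      "bird_id": "B03_3",
      "origin": "N03",
      "treatment": "control",
      "rearing": "N03"
    },
    {
      "bird_id": "B03_4",
      "origin": "N03",
      "treatment": "control",
      "rearing": "N03"
    },
    {
      "bird_id": "B03_5",
      "origin": "N03",
      "treatment": "control",
      "rearing": "N03"
    },
    {
      "bird_id": "B03_6",
      "origin": "N03",
      "treatment": "control",
      "rearing": "N03"
    },
    {
      "bird_id": "B04_1",
      "origin": "N04",
      "treatment": "control",
      "rearing": "N04"
    },
    {
      "bird_id": "B04_2",
      "origin": "N04",
      "treatment": "control",
      "rearing": "N04"
    },
    {
      "bird_id": "B04_3",
      "origin": "N04",
      "treatment": "control",
      "rearing": "N04"
    },
    {
      "bird_id": "B04_4",
      "origin": "N04",
      "treatment": "control",
      "rearing": "N04"
    },
    {
      "bird_id": "B04_5",
      "origin": "N04",
      "treatment": "control",
      "rearing": "N04"
    },
    {
      "bird_id": "B04_6",
      "origin": "N04",
      "treatment": "control",
      "rearing": "N04"
    }
  ]
}
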
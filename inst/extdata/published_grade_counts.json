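{
  "description": "Per-side Gertzbein-Robbins grade counts from a published clinical comparison of AI-planned versus freehand pedicle screw placement (45 patients, 208 screws per arm, thoracolumbar segments).",
  "schema_version": 1,
  "counts": {
    "ai": {
      "L": {"A": 94, "B": 9, "C": 1, "D": 0, "E": 0},
      "R": {"A": 83, "B": 18, "C": 3, "D": 0, "E": 0}
    },
    "freehand": {
      "L": {"A": 73, "B": 27, "C": 4, "D": 0, "E": 0},
      "R": {"A": 62, "B": 29, "C": 11, "D": 2, "E": 0}
    }
  }
}
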
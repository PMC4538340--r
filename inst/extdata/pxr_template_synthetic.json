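{
  "version": "1.0",
  "comment": "Five-feature screening template carrying the PXR agonist type signature. The geometry is SYNTHETIC placeholder geometry (well-separated, deliberately asymmetric centres for fixtures and demos), not coordinates fitted to any receptor structure.",
  "features": [
    {"types": ["Hyd", "Acc"], "center": [0.0, 0.0, 0.0], "tolerance": 1.2},
    {"types": ["Acc", "Acc2", "Don2"], "center": [6.2, 0.8, 0.4], "tolerance": 1.2},
    {"types": ["Hyd", "Acc2"], "center": [1.8, 5.9, -1.2], "tolerance": 1.2},
    {"types": ["Hyd", "Acc"], "center": [-4.1, 3.2, 2.1], "tolerance": 1.2},
    {"types": ["ARO", "Hyd"], "center": [2.4, -4.6, 3.3], "tolerance": 1.2}
  ],
  "excluded_volumes": [
    {"center": [11.26, 1.06, 4.42], "radius": 1.0},
    {"center": [8.331, 8.131, -2.58], "radius": 1.0},
    {"center": [1.26, 11.06, 4.42], "radius": 1.0},
    {"center": [-5.811, 8.131, -2.58], "radius": 1.0},
    {"center": [-8.74, 1.06, 4.42], "radius": 1.0},
    {"center": [-5.811, -6.011, -2.58], "radius": 1.0},
    {"center": [1.26, -8.94, 4.42], "radius": 1.0},
    {"center": [8.331, -6.011, -2.58], "radius": 1.0}
  ],
  "min_features_required": 5
}
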
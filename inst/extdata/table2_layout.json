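{
  "comment": "Five-antenna fattening-pen layout. distance_matrix: published center-to-center Euclidean distances (m, printed at 0.1 m). locations: synthetic planar coordinates realizing that matrix to within 0.014 m (least-squares embedding, trough at origin); coordinates are a reconstruction, not surveyed positions.",
  "locations": {
    "trough": [0.0, 0.0],
    "drinker1": [-6.85, 1.425],
    "drinker2": [-7.507, -0.021],
    "drinker3": [-7.185, -1.267],
    "playing_device": [-5.101, -1.011]
  },
  "distance_matrix": {
    "ids": ["trough", "drinker1", "drinker2", "drinker3", "playing_device"],
    "meters": [
      [0.0, 7.0, 7.5, 7.3, 5.2],
      [7.0, 0.0, 1.6, 2.7, 3.0],
      [7.5, 1.6, 0.0, 1.3, 2.6],
      [7.3, 2.7, 1.3, 0.0, 2.1],
      [5.2, 3.0, 2.6, 2.1, 0.0]
    ]
  }
}
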
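{
  "type": "FeatureCollection",
  "features": [
    {
      "type": "Feature",
      "properties": { "name": "north" },
      "geometry": {
        "type": "Polygon",
        "coordinates": [[[102.5, 16.5], [107.5, 16.5], [107.5, 23.0], [102.5, 23.0], [102.5, 16.5]]]
      }
    },
    {
      "type": "Feature",
      "properties": { "name": "south" },
      "geometry": {
        "type": "Polygon",
        "coordinates": [[[104.5, 8.5], [109.5, 8.5], [109.5, 16.5], [104.5, 16.5], [104.5, 8.5]]]
      }
    }
  ]
}
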
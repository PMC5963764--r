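{"type":"FeatureCollection","features":[{"type":"Feature","properties":{"group":1},"geometry":{"type":"MultiPolygon","coordinates":{"pt.1":[[[1000,553.60179],[519.780578,602.927329],[426.198611,477.547236],[552.513798,0],[1000,0],[1000,553.60179]]]}}},{"type":"Feature","properties":{"group":2},"geometry":{"type":"MultiPolygon","coordinates":{"pt.2":[[[1000,1000],[474.688084,1000],[519.780578,602.927329],[1000,553.60179],[1000,1000]]]}}},{"type":"Feature","properties":{"group":3},"geometry":{"type":"MultiPolygon","coordinates":{"pt.3":[[[474.688084,1000],[0,1000],[0,513.313206],[426.198611,477.547236],[519.780578,602.927329],[474.688084,1000]]]}}},{"type":"Feature","properties":{"group":4},"geometry":{"type":"MultiPolygon","coordinates":{"pt.4":[[[426.198611,477.547236],[0,513.313206],[0,0],[552.513798,0],[426.198611,477.547236]]]}}}]}
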
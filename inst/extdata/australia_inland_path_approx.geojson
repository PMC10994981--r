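{"type":"FeatureCollection","features":[{"type":"Feature","properties":{"role":"path"},"geometry":{"type":"LineString","coordinates":[[115,-26.5],[115.8,-29.5],[116.5,-32],[117.5,-34],[120,-33.5],[123,-32.5],[126,-31.8],[129,-31.2],[132,-31.3],[134.5,-32],[137,-33.5],[139.5,-34.8],[142,-36],[144.3,-37.2],[146.5,-37],[148.5,-36],[150,-34],[150.5,-32],[151,-30],[151.5,-28],[151.8,-26.5]]}},{"type":"Feature","properties":{"role":"origin"},"geometry":{"type":"Point","coordinates":[144.3,-37.2]}}]}
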
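{
  "layout_id": "A",
  "stimulus_size": [1280, 1024],
  "regions": [
    {
      "label": "A",
      "name": "I",
      "rect": [40, 80, 330, 280],
      "is_lead": true
    },
    {
      "label": "B",
      "name": "II",
      "rect": [40, 290, 330, 490],
      "is_lead": true
    },
    {
      "label": "C",
      "name": "III",
      "rect": [40, 500, 330, 700],
      "is_lead": true
    },
    {
      "label": "D",
      "name": "aVR",
      "rect": [340, 80, 630, 280],
      "is_lead": true
    },
    {
      "label": "E",
      "name": "aVL",
      "rect": [340, 290, 630, 490],
      "is_lead": true
    },
    {
      "label": "F",
      "name": "aVF",
      "rect": [340, 500, 630, 700],
      "is_lead": true
    },
    {
      "label": "G",
      "name": "V1",
      "rect": [640, 80, 930, 280],
      "is_lead": true
    },
    {
      "label": "H",
      "name": "V2",
      "rect": [640, 290, 930, 490],
      "is_lead": true
    },
    {
      "label": "I",
      "name": "V3",
      "rect": [640, 500, 930, 700],
      "is_lead": true
    },
    {
      "label": "J",
      "name": "V4",
      "rect": [940, 80, 1230, 280],
      "is_lead": true
    },
    {
      "label": "K",
      "name": "V5",
      "rect": [940, 290, 1230, 490],
      "is_lead": true
    },
    {
      "label": "L",
      "name": "V6",
      "rect": [940, 500, 1230, 700],
      "is_lead": true
    },
    {
      "label": "M",
      "name": "rhythm II",
      "rect": [40, 710, 1230, 800],
      "is_lead": true
    },
    {
      "label": "N",
      "name": "annotation",
      "rect": [40, 5, 1230, 60],
      "is_lead": false
    }
  ],
  "key_leads": []
}
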
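{
  "protocols": [
    {
      "name": "Group 1",
      "scenes": [
        {"id": "00 MainMenu", "param": "0"},
        {"id": "01 Baseline", "param": "0"},
        {"id": "02 Experiment", "param": "1"},
        {"id": "03 Questionnaire", "param": "TLX"}
      ]
    },
    {
      "name": "Group 2",
      "scenes": [
        {"id": "00 MainMenu", "param": "0"},
        {"id": "01 Baseline", "param": "0"},
        {"id": "02 Experiment", "param": "2"},
        {"id": "03 Questionnaire", "param": "TLX"}
      ]
    }
  ]
}
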
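{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "prfRecon pipeline report",
  "type": "object",
  "required": ["config", "configHash", "perObserver", "summary"],
  "properties": {
    "config": { "type": "object" },
    "configHash": { "type": "string" },
    "perObserver": { "type": ["array", "object"] },
    "profiles": { "type": ["array", "object"] },
    "summary": {
      "type": "object",
      "required": ["experiment", "muDiffMean"],
      "properties": {
        "experiment": { "type": "string" },
        "muDiffMean": { "type": "number" },
        "muDiffPerObserver": { "type": ["array", "number"] },
        "pairedT": { "type": "object" }
      }
    }
  }
}
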
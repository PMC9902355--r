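{
  "traits": [
    {
      "trait_id": "yield",
      "crop": "maize",
      "name": "Plot yield",
      "unit": "kg",
      "data_type": "numeric",
      "min_value": 0,
      "max_value": 100,
      "decimals": 2,
      "aggregation": "mean",
      "method": "Weight of shelled grain per plot at 14% moisture"
    },
    {
      "trait_id": "plant_height",
      "crop": "maize",
      "name": "Plant height",
      "unit": "m",
      "data_type": "numeric",
      "min_value": 0.5,
      "max_value": 5,
      "decimals": 2,
      "aggregation": "mean",
      "method": "Ground level to tassel tip, 10 plants per plot"
    },
    {
      "trait_id": "grain_weight",
      "crop": "maize",
      "name": "100-grain weight",
      "unit": "g",
      "data_type": "numeric",
      "min_value": 10,
      "max_value": 60,
      "decimals": 2,
      "aggregation": "mean"
    },
    {
      "trait_id": "sowing_date",
      "crop": "maize",
      "name": "Sowing date",
      "data_type": "date",
      "aggregation": "none"
    },
    {
      "trait_id": "plant_type",
      "crop": "maize",
      "name": "Plant type",
      "data_type": "enumeration",
      "allowed_values": ["compact", "semi-compact", "flat"],
      "aggregation": "none"
    }
  ],
  "rules": [
    { "rule_type": "range", "trait_id": "plant_height",
      "params": { "min": 0.5, "max": 5 } },
    { "rule_type": "range", "trait_id": "yield",
      "params": { "min": 0, "max": 100 } },
    { "rule_type": "format", "trait_id": "sowing_date",
      "params": { "kind": "date" } },
    { "rule_type": "format", "trait_id": "yield",
      "params": { "kind": "decimal", "decimals": 2 } },
    { "rule_type": "enumeration", "trait_id": "plant_type",
      "params": { "allowed": ["compact", "semi-compact", "flat"] } },
    { "rule_type": "consistency", "trait_id": "yield",
      "params": { "partner_trait_id": "grain_weight",
                  "a": 0.5, "b": 0, "tolerance": 5 } },
    { "rule_type": "statistic", "trait_id": "yield",
      "params": { "lower": 0, "upper": 10 } }
  ],
  "criteria": {
    "min_y": 5.0, "min_y1": 3.0, "min_y2": 3.0,
    "min_q1": 720, "min_q2": 69.0, "min_q3": 8.0, "min_q4": 3.0,
    "max_r1": 8.0, "max_r2": 20, "max_p": 2.0,
    "veto_diseases": ["Leaf blight", "Stem rot", "Ear rot",
                      "Head smut", "Gray spot"]
  }
}
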
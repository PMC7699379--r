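[
  {"scale": "HGS", "item": "ears", "label": "Stiffly backward ears", "min_score": 0, "max_score": 2, "physiological": false},
  {"scale": "HGS", "item": "orb", "label": "Orbital tightening", "min_score": 0, "max_score": 2, "physiological": false},
  {"scale": "HGS", "item": "ten", "label": "Tension above the eye area", "min_score": 0, "max_score": 2, "physiological": false},
  {"scale": "HGS", "item": "chew", "label": "Prominent strained chewing muscles", "min_score": 0, "max_score": 2, "physiological": false},
  {"scale": "HGS", "item": "mouth", "label": "Mouth strained and pronounced chin", "min_score": 0, "max_score": 2, "physiological": false},
  {"scale": "HGS", "item": "nost", "label": "Strained nostrils and flattening of the profile", "min_score": 0, "max_score": 2, "physiological": false},
  {"scale": "EQUUS_FAP", "item": "head", "label": "Head", "min_score": 0, "max_score": 2, "physiological": false},
  {"scale": "EQUUS_FAP", "item": "eye", "label": "Eyelids", "min_score": 0, "max_score": 2, "physiological": false},
  {"scale": "EQUUS_FAP", "item": "focus", "label": "Focus", "min_score": 0, "max_score": 2, "physiological": false},
  {"scale": "EQUUS_FAP", "item": "nost", "label": "Nostrils", "min_score": 0, "max_score": 2, "physiological": false},
  {"scale": "EQUUS_FAP", "item": "mouth", "label": "Corners mouth/lips", "min_score": 0, "max_score": 2, "physiological": false},
  {"scale": "EQUUS_FAP", "item": "tone", "label": "Muscle tone head", "min_score": 0, "max_score": 2, "physiological": false},
  {"scale": "EQUUS_FAP", "item": "fleya", "label": "Flehmen and/or yawning", "min_score": 0, "max_score": 2, "physiological": false},
  {"scale": "EQUUS_FAP", "item": "teeth", "label": "Teeth grinding and/or moaning", "min_score": 0, "max_score": 2, "physiological": false},
  {"scale": "EQUUS_FAP", "item": "ears", "label": "Ears", "min_score": 0, "max_score": 2, "physiological": false},
  {"scale": "EPS", "item": "pf", "label": "Pain face", "min_score": 0, "max_score": 4, "physiological": false},
  {"scale": "EPS", "item": "gross", "label": "Gross pain behavior", "min_score": 0, "max_score": 4, "physiological": false},
  {"scale": "EPS", "item": "act", "label": "Activity", "min_score": 0, "max_score": 4, "physiological": false},
  {"scale": "EPS", "item": "loc", "label": "Location in the stall", "min_score": 0, "max_score": 4, "physiological": false},
  {"scale": "EPS", "item": "pos", "label": "Posture/weight bearing", "min_score": 0, "max_score": 4, "physiological": false},
  {"scale": "EPS", "item": "head", "label": "Head position", "min_score": 0, "max_score": 4, "physiological": false},
  {"scale": "EPS", "item": "att", "label": "Attention towards painful area", "min_score": 0, "max_score": 4, "physiological": false},
  {"scale": "EPS", "item": "int", "label": "Interactive behavior", "min_score": 0, "max_score": 4, "physiological": false},
  {"scale": "EPS", "item": "food", "label": "Response to food", "min_score": 0, "max_score": 4, "physiological": false},
  {"scale": "CPS", "item": "kick", "label": "Kicking abdomen", "min_score": 0, "max_score": 3, "physiological": false},
  {"scale": "CPS", "item": "paw", "label": "Pawing on the floor", "min_score": 0, "max_score": 3, "physiological": false},
  {"scale": "CPS", "item": "head", "label": "Head movement", "min_score": 0, "max_score": 3, "physiological": false},
  {"scale": "CPS", "item": "app", "label": "Appearance", "min_score": 0, "max_score": 3, "physiological": false},
  {"scale": "CPS", "item": "pos", "label": "Posture", "min_score": 0, "max_score": 3, "physiological": false},
  {"scale": "CPS", "item": "app2", "label": "Appetite", "min_score": 0, "max_score": 3, "physiological": false},
  {"scale": "CPS", "item": "sweat", "label": "Sweating", "min_score": 0, "max_score": 3, "physiological": false},
  {"scale": "CPS", "item": "int", "label": "Interactive behavior", "min_score": 0, "max_score": 3, "physiological": false},
  {"scale": "CPS", "item": "palp", "label": "Response to palpation of painful area", "min_score": 0, "max_score": 3, "physiological": false},
  {"scale": "CPS", "item": "temp", "label": "Rectal temperature", "min_score": 0, "max_score": 3, "physiological": true},
  {"scale": "CPS", "item": "heart_rate", "label": "Heart rate", "min_score": 0, "max_score": 3, "physiological": true},
  {"scale": "CPS", "item": "resp_rate", "label": "Respiratory rate", "min_score": 0, "max_score": 3, "physiological": true},
  {"scale": "CPS", "item": "digestive", "label": "Digestive sounds", "min_score": 0, "max_score": 3, "physiological": true}
]
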
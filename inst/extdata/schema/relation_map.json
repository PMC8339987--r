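{
  "At": [
    ["Location", "Mass"],
    ["Location", "LymphNode"],
    ["Location", "Effusion"],
    ["Location", "PAOP"]
  ],
  "SizeOf": [
    ["Size", "Mass"],
    ["Size", "LymphNode"]
  ],
  "Negate": [
    ["Negation", "Mass"],
    ["Negation", "LymphNode"],
    ["Negation", "Bronchus"],
    ["Negation", "Pleura"],
    ["Negation", "Vessel"],
    ["Negation", "VertebralBody"],
    ["Negation", "Effusion"],
    ["Negation", "PAOP"]
  ],
  "Related": [
    ["Mass", "Density"],
    ["Mass", "Enhancement"],
    ["Mass", "Shape"],
    ["Mass", "Bronchus"],
    ["Mass", "Pleura"],
    ["Mass", "Vessel"],
    ["Mass", "VertebralBody"],
    ["Mass", "PAOP"],
    ["Mass", "Effusion"]
  ]
}
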
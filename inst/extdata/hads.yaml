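instrument: HADS
node_granularity: per_item
community:
  anxiety: anxiety
  depression: depression
# Responses are assumed recorded in scored direction (0 = least symptomatic,
# 3 = most symptomatic), so no reverse-coded items are declared; add item ids
# under `reverse:` if your file stores raw endorsements instead.
items:
  - {id: H1,  node: Tns, label: "Tense or wound up",                      min: 0, max: 3}
  - {id: H2,  node: Enj, label: "Still enjoy the things I used to enjoy", min: 0, max: 3}
  - {id: H3,  node: Fgt, label: "Frightened feeling something awful is about to happen", min: 0, max: 3}
  - {id: H4,  node: Fnn, label: "Can laugh and see the funny side of things", min: 0, max: 3}
  - {id: H5,  node: Wrr, label: "Worrying thoughts go through my mind",   min: 0, max: 3}
  - {id: H6,  node: Chr, label: "Feel cheerful",                          min: 0, max: 3}
  - {id: H7,  node: Rlx, label: "Can sit at ease and feel relaxed",       min: 0, max: 3}
  - {id: H8,  node: Slw, label: "Feel as if I am slowed down",            min: 0, max: 3}
  - {id: H9,  node: Btt, label: "Frightened feeling like butterflies in the stomach", min: 0, max: 3}
  - {id: H10, node: App, label: "Lost interest in my appearance",         min: 0, max: 3}
  - {id: H11, node: Rst, label: "Restless, as if I have to be on the move", min: 0, max: 3}
  - {id: H12, node: Frw, label: "Look forward with enjoyment to things",  min: 0, max: 3}
  - {id: H13, node: Pnc, label: "Sudden feelings of panic",               min: 0, max: 3}
  - {id: H14, node: Bok, label: "Can enjoy a good book or programme",     min: 0, max: 3}
subscales:
  - id: anxiety
    label: Anxiety
    items: [H1, H3, H5, H7, H9, H11, H13]
  - id: depression
    label: Depression
    items: [H2, H4, H6, H8, H10, H12, H14]
reverse: []
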
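instrument: DERS
node_granularity: per_subscale
community: DER
items:
  - {id: D1,  label: "Clear about my feelings",                        min: 1, max: 5}
  - {id: D2,  label: "Pay attention to how I feel",                    min: 1, max: 5}
  - {id: D3,  label: "Emotions feel overwhelming and out of control",  min: 1, max: 5}
  - {id: D4,  label: "No idea how I am feeling",                       min: 1, max: 5}
  - {id: D5,  label: "Difficulty making sense of my feelings",         min: 1, max: 5}
  - {id: D6,  label: "Attentive to my feelings",                       min: 1, max: 5}
  - {id: D7,  label: "Know exactly how I am feeling",                  min: 1, max: 5}
  - {id: D8,  label: "Care about what I am feeling",                   min: 1, max: 5}
  - {id: D9,  label: "Confused about how I feel",                      min: 1, max: 5}
  - {id: D10, label: "When upset, acknowledge my emotions",            min: 1, max: 5}
  - {id: D11, label: "When upset, angry with myself for feeling so",   min: 1, max: 5}
  - {id: D12, label: "When upset, embarrassed for feeling that way",   min: 1, max: 5}
  - {id: D13, label: "When upset, difficulty getting work done",       min: 1, max: 5}
  - {id: D14, label: "When upset, become out of control",              min: 1, max: 5}
  - {id: D15, label: "When upset, believe I will remain that way",     min: 1, max: 5}
  - {id: D16, label: "When upset, believe I will end up very depressed", min: 1, max: 5}
  - {id: D17, label: "When upset, believe my feelings are valid",      min: 1, max: 5}
  - {id: D18, label: "When upset, difficulty focusing on other things", min: 1, max: 5}
  - {id: D19, label: "When upset, feel out of control",                min: 1, max: 5}
  - {id: D20, label: "When upset, can still get things done",          min: 1, max: 5}
  - {id: D21, label: "When upset, ashamed for feeling that way",       min: 1, max: 5}
  - {id: D22, label: "When upset, know I can find a way to feel better", min: 1, max: 5}
  - {id: D23, label: "When upset, feel weak",                          min: 1, max: 5}
  - {id: D24, label: "When upset, can remain in control of behavior",  min: 1, max: 5}
  - {id: D25, label: "When upset, feel guilty for feeling that way",   min: 1, max: 5}
  - {id: D26, label: "When upset, difficulty concentrating",           min: 1, max: 5}
  - {id: D27, label: "When upset, difficulty controlling behavior",    min: 1, max: 5}
  - {id: D28, label: "When upset, believe nothing can make me feel better", min: 1, max: 5}
  - {id: D29, label: "When upset, irritated with myself for feeling so", min: 1, max: 5}
  - {id: D30, label: "When upset, feel very bad about myself",         min: 1, max: 5}
  - {id: D31, label: "When upset, wallowing is all I can do",          min: 1, max: 5}
  - {id: D32, label: "When upset, lose control over my behavior",      min: 1, max: 5}
  - {id: D33, label: "When upset, difficulty thinking about anything else", min: 1, max: 5}
  - {id: D34, label: "When upset, take time to figure out my feelings", min: 1, max: 5}
  - {id: D35, label: "When upset, takes a long time to feel better",   min: 1, max: 5}
  - {id: D36, label: "When upset, emotions feel overwhelming",         min: 1, max: 5}
subscales:
  - id: NNC
    label: Nonacceptance of emotional responses
    items: [D11, D12, D21, D23, D25, D29]
  - id: GOL
    label: Difficulties engaging in goal-directed behavior
    items: [D13, D18, D20, D26, D33]
  - id: IMP
    label: Impulse control difficulties
    items: [D3, D14, D19, D24, D27, D32]
  - id: AWR
    label: Lack of emotional awareness
    items: [D2, D6, D8, D10, D17, D34]
  - id: STR
    label: Limited access to emotion regulation strategies
    items: [D15, D16, D22, D28, D30, D31, D35, D36]
  - id: CLR
    label: Lack of emotional clarity
    items: [D1, D4, D5, D7, D9]
reverse: [D1, D2, D6, D7, D8, D10, D17, D20, D22, D24, D34]
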
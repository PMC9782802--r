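stages: [L3, L4, L5, pupa, adult_female, adult_male]
entry: L3
reproductive: adult_female
adult_female: adult_female
adult_male: adult_male
death: dead
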
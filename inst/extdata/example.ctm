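# synthetic example alignment: two short utterances
spk1 1 0.00 0.12 a
spk1 1 0.12 0.10 b
spk1 1 0.22 0.45 sil
spk1 1 0.67 0.15 c
spk1 1 0.82 0.20 fp
spk1 1 1.02 0.11 d
spk2 1 0.00 0.30 sil
spk2 1 0.30 0.14 a
spk2 1 0.44 0.52 sil
spk2 1 0.96 0.13 e
spk2 1 1.09 0.09 f
spk2 1 1.18 0.40 sil
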
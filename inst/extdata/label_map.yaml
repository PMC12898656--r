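# Recognizer label -> pause category bindings.
silent_labels:
  - sil
  - sp
  - pau
  - "<sil>"
filled_labels:
  - fp
  - hes
  - um
  - uh
  - "ööö"
default_category: phone
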
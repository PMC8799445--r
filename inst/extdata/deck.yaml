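# six 16-strip holders on the deck: 96 strips per run
wells_per_strip: 2
holders:
  - {holder_id: H1, strip_capacity: 16, type: strips}
  - {holder_id: H2, strip_capacity: 16, type: strips}
  - {holder_id: H3, strip_capacity: 16, type: strips}
  - {holder_id: H4, strip_capacity: 16, type: strips}
  - {holder_id: H5, strip_capacity: 16, type: strips}
  - {holder_id: H6, strip_capacity: 16, type: strips}
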
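# 16 capture x 16 detection antibody pair screen in three matrices
# (antigen-free plasma, plasma spiked with ag1, plasma spiked with ag2),
# run in technical duplicate: 16 x 16 x 3 x 2 = 1536 strips.
replicates: 2
factors:
  - name: capture
    role: capture_antibody
    levels: [MAb001, MAb002, MAb003, MAb004, MAb005, MAb006, MAb007, MAb008,
             MAb009, MAb010, MAb011, MAb012, MAb013, MAb014, MAb015, MAb016]
  - name: detection
    role: detection_antibody
    levels: [MAb001, MAb002, MAb003, MAb004, MAb005, MAb006, MAb007, MAb008,
             MAb009, MAb010, MAb011, MAb012, MAb013, MAb014, MAb015, MAb016]
  - name: matrix
    role: sample_matrix
    levels: [blank, ag1, ag2]
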
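stock_id,component,concentration,volume
conjugate,latex_conjugate,100,1000000
sample,pooled_plasma,0,1000000
buffer,.diluent,0,1000000
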
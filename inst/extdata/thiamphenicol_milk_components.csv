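term,const_var,prop_var
repeatability,0.90760,0.00000
block,0.88789,0.00000
batch,0.00000,0.00004
storage,1.06201,0.00000
technician,1.52630,0.00000
mixer,0.00000,0.00029
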
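term,const_var,prop_var
repeatability,0.00000,0.01096
block,0.00142,0.00524
breeding,0.00118,0.00048
operator,0.00749,0.00447
hplc,0.00000,0.00000
extract_storage,0.00258,0.00000
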
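sample_id,dataset,environment,Eh_mV,pH,T_C,O2_value,O2_unit
demo,winogradsky,sediment,-150,6.2,25,0.4,mg_L
top,winogradsky,sediment,310,7.1,25,95,pct_sat
swi,winogradsky,sediment,45,6.8,25,2.1,mg_L
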
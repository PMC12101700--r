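"origin_country","age","gender","exposure","mu_hat","d_hat"
"A",40,"F",1000,0.001,1
"A",41,"M",2000,0.002,4
"B",40,"F",1500,0.0015,2.25
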
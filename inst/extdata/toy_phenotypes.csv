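sample_id,trait,value
s1,yield,1.2
s2,yield,0.4
s3,yield,-0.3
s4,yield,2.1
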
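>synthetic_example
ACGUACGUACGUACGUACGUACGUACGUACGUACGUACGUACGUACGU
((((...)))) ( -5.40) 17 z= -1.20
(((....))) ( -2.10) 3 z=  0.50
((((....)))) ( -3.20) 40
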
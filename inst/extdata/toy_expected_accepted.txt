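c01
c03
c05
c06
c09
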
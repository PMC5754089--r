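((A:1.0,B:1.0):0.5,C:1.5);
((A:1.1,B:0.9):0.6,C:1.4);
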
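#NEXUS
[ID: 0123456789]
[This is a small synthetic example in the MrBayes trees dialect.]
begin trees;
   translate
      1 A,
      2 B,
      3 C,
      4 D;
   tree gen.1 = [&U] ((1:0.010[&length_mean=0.010],2:0.020):0.005,3:0.030,4:0.040);
   tree gen.2 = [&U] ((1:0.011,2:0.021):0.006,3:0.031,4:0.041);
   tree gen.3 = [&U] ((1:0.012,2:0.022):0.007,3:0.032,4:0.042);
end;
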
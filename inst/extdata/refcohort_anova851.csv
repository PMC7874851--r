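source,ss,df,ms,F,p
Columns,1.70,9,0.189,10.2,<0.001
Error,2.60,140,0.0186,,
Total,4.31,149,,,
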
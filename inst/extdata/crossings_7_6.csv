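x,y,z
-3.68122,2.1618,0.520849
-2.31313,4.52637,-0.526226
-0.291898,-0.0329635,0.5289
-0.000160251,-3.82999,-0.657526
1.29451,3.02755,-0.309725
2.99467,4.45183,0.450002
3.79753,2.50471,-0.482759
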
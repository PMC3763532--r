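(((((dme:0.15,(dsi:0.08,dps:0.08)SimPse:0.07)Drosophila:0.25,aga:0.4)Diptera:0.2,tca:0.6)Insects:0.2,lgi:0.8)Protostomes:0.2,hsa:1.0)Metazoans;
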
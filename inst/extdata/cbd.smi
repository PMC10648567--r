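CCCCCc1cc(O)c(C2C=C(C)CCC2C(=C)C)c(O)c1 CBD
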
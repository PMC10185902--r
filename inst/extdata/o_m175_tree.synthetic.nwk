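(C,(N,(((((O1a1a1)O1a1a)O1a1)O1a,((((((((((((((O1b1a1a1a1a1a1a1a)O1b1a1a1a1a1a1a1)O1b1a1a1a1a1a1a)O1b1a1a1a1a1a1)O1b1a1a1a1a1a)O1b1a1a1a1a1)O1b1a1a1a1a)O1b1a1a1a1)O1b1a1a1a)O1b1a1a1)O1b1a1a)O1b1a1,O1b1a2)O1b1a)O1b1,(((O1b2a1a)O1b2a1)O1b2a)O1b2)O1b)O1,((((((((O2a1a1a1a1)O2a1a1a1a)O2a1a1a1)O2a1a1a)O2a1a1)O2a1a,(((((((O2a1b1a1a1a1)O2a1b1a1a1a)O2a1b1a1a1)O2a1b1a1a)O2a1b1a1)O2a1b1a)O2a1b1)O2a1b)O2a1,(((O2a2a1a)O2a2a1)O2a2a,((((((((O2a2b1a1a1a4a)O2a2b1a1a1a4)O2a2b1a1a1a)O2a2b1a1a1)O2a2b1a1a)O2a2b1a1,(((O2a2b1a2a1a)O2a2b1a2a1)O2a2b1a2a)O2a2b1a2)O2a2b1a)O2a2b1)O2a2b)O2a2,O2a4)O2a)O2)O)NO)Y;
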
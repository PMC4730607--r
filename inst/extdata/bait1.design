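# Randomized bait: 8 random bases, fixed TAAT, 8 random bases.
name = bait1
adapter5 = TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG
adapter3 = CTGTCTCTTATACACATCTCCGAGCCCACGAGAC
positions = NNNNNNNNTAATNNNNNNNN
retention = 0.91
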
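# Doped bait: 11-bp core synthesized around TAATTTAATCA (91% consensus,
# 3% each alternative), 3 uniform-random bases on each side.
name = bait2
adapter5 = TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG
adapter3 = CTGTCTCTTATACACATCTCCGAGCCCACGAGAC
positions = NNNtaatttaatcaNNN
retention = 0.91
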
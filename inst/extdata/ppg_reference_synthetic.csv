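expected_mz,expected_relative_intensity
443.33,0.35
501.37,0.62
559.42,1.00
617.46,0.74
675.50,0.48
733.54,0.22
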
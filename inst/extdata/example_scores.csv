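item,ASE,AffinitydG,LondondG
cpd_001,-12.4,-9.8,-11.1
cpd_002,-10.1,-10.5,-9.7
cpd_003,-11.8,-8.9,-10.9
cpd_004,-9.2,-9.1,-8.8
cpd_005,-13.0,-11.2,-12.0
cpd_006,-8.7,-7.9,-9.1
cpd_007,-10.9,-10.1,-10.2
cpd_008,-9.9,-8.4,-8.5
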
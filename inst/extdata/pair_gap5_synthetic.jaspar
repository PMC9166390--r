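>pair_gap5_synthetic TGACGTCA-n5-CACGTGAC
A [ 3 3 91 3 3 3 3 91 25 25 25 25 25 3 91 3 3 3 3 91 3 ]
C [ 3 3 3 91 3 3 91 3 25 25 25 25 25 91 3 91 3 3 3 3 91 ]
G [ 3 91 3 3 91 3 3 3 25 25 25 25 25 3 3 3 91 3 91 3 3 ]
T [ 91 3 3 3 3 91 3 3 25 25 25 25 25 3 3 3 3 91 3 3 3 ]
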
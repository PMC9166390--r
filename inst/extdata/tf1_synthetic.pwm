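# synthetic bZIP-like motif TGACGTCA (counts)
3 3 91 3 3 3 3 91
3 3 3 91 3 3 91 3
3 91 3 3 91 3 3 3
91 3 3 3 3 91 3 3
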
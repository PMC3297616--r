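predicted,observed_absent,observed_present
absent,403,90
present,24,75
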
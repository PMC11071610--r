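subject_id,truth_value
A,3
B,10
C,27
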
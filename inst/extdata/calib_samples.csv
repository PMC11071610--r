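subject_id,sample_id,metric_value
A,1,1
A,2,2
A,3,3
A,4,4
A,5,5
B,1,11
B,2,12
B,3,13
B,4,14
B,5,15
C,1,20
C,2,22
C,3,24
C,4,26
C,5,28
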
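subject_id,sample_id,metric_value
T,1,5
T,2,6
T,3,7
T,4,8
T,5,9
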
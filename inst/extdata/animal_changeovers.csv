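animal_id,repeat_no,relative_start_min,scan_duration_min,scan_id
C4,1,0,NA,ID16
C3,1,10,NA,ID17
C4,2,11,NA,ID18
C3,2,9,NA,ID19
C4,3,8,NA,ID20
C3,3,8,4,ID21
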
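"baseline_ng_ml","dose_iu_d","achieved_ng_ml"
11,400,25
14,400,18
17,400,21
20,400,24
23,400,27
26,400,29
29,400,33
33,400,36
36,400,39
40,400,43
11,1000,29
14,1000,24
17,1000,28
20,1000,29
23,1000,32
26,1000,35
29,1000,37
33,1000,40
36,1000,43
40,1000,46
11,2000,31
14,2000,33
17,2000,35
20,2000,37
23,2000,40
26,2000,42
29,2000,44
33,2000,47
36,2000,49
40,2000,52
11,4000,45
14,4000,47
17,4000,49
20,4000,50
23,4000,51
26,4000,53
29,4000,55
33,4000,57
36,4000,59
40,4000,61
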
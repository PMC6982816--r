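patient_id,actual_events,predicted,truly_predicted,falsely_predicted,not_predicted
1,0,3,0,3,0
2,2,1,1,0,1
3,1,2,2,0,0
4,0,4,0,4,0
5,0,1,0,1,0
6,0,0,0,0,0
7,0,0,0,0,0
8,0,0,0,0,0
9,3,7,1,6,2
10,1,3,0,3,1
11,0,0,0,0,0
12,3,5,3,2,1
13,5,7,6,1,3
14,0,3,0,3,0
15,0,4,0,4,0
16,6,5,4,1,2
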
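couple_uid,person_uid,studyday_id,moment_id,item,value
1,1,1,1,1,4
1,1,1,1,2,5
1,1,1,2,1,5
1,1,1,2,2,4
1,1,2,1,1,5
1,1,2,1,2,1
1,1,2,2,1,6
1,1,2,2,2,4
1,2,1,1,1,5
1,2,1,1,2,4
1,2,1,2,1,3
1,2,1,2,2,5
1,2,2,1,1,2
1,2,2,1,2,5
1,2,2,2,1,5
1,2,2,2,2,2
2,3,1,1,1,5
2,3,1,1,2,6
2,3,1,2,1,3
2,3,1,2,2,4
2,3,2,1,1,5
2,3,2,1,2,4
2,3,2,2,1,4
2,3,2,2,2,2
2,4,1,1,1,2
2,4,1,1,2,5
2,4,1,2,1,5
2,4,1,2,2,3
2,4,2,1,1,6
2,4,2,1,2,5
2,4,2,2,1,4
2,4,2,2,2,1
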
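participant_id,arm,total_pre,B_pre,C_pre,D_pre,E_pre,total_post,B_post,C_post,D_post,E_post,total_fup,B_fup,C_fup,D_fup,E_fup
A1,HBOT,40,10,4,14,12,26,7,2,9,8,20,5,2,7,6
A2,HBOT,50,13,5,17,15,20,5,2,7,6,15,4,1,5,5
A3,HBOT,44,11,4,15,14,22,6,2,8,6,26,7,3,9,7
A4,HBOT,36,9,3,13,11,30,8,3,10,9,33,8,3,12,10
A5,HBOT,48,12,5,16,15,42,11,4,14,13,40,10,4,14,12
A6,HBOT,30,8,3,10,9,27,7,3,9,8,29,7,3,10,9
S1,sham,45,11,5,15,14,44,11,4,15,14,45,11,5,15,14
S2,sham,42,11,4,14,13,25,6,2,9,8,35,9,3,12,11
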
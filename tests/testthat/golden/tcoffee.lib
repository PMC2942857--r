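! TC_LIB_FORMAT_01
3
alpha 7 MKVLITA
beta 7 MKVLSTA
gamma 7 GMKVLTT
#1 2
1 1 300
2 2 300
4 4 300
#1 3
1 2 300
2 3 300
#2 3
1 2 300
2 3 300
! SEQ_1_TO_N
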
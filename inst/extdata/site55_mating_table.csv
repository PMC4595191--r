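pairs_AvM_AvF,pairs_AvM_AhF,pairs_AhM_AvF,pairs_AhM_AhF,single_Av,single_Ah
40,4,9,20,9,8
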
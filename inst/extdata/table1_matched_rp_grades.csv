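modality,rp_grade,count
IMRT,0,14
IMRT,1,10
IMRT,2,7
IMRT,3,1
VMAT,0,19
VMAT,1,10
VMAT,2,2
VMAT,3,1
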
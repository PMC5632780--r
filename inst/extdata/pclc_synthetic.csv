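"intrusion","dreams","flash","upset","physior"
4,5,1,1,5
5,1,2,1,2
1,,1,4,1
4,5,4,2,1
2,5,2,1,1
2,1,4,2,3
3,2,3,1,1
1,2,4,5,3
3,4,1,2,
3,1,3,5,1
2,5,1,4,1
3,5,4,2,2
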
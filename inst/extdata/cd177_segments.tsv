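# cd177conv-schema: segments/v1
exon	c_start	c_end	offset
1	1	60	40
2	61	140	128
3	141	300	800
4	301	460	1610
5	461	650	1817
6	651	770	5973
7	771	791	6710
7	792	939	6711
8	940	1100	6946
9	1101	1314	7344
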
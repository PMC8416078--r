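ingredient	taxid	proportion
Angelicae Sinensis Radix (Danggui)	101	14.81
Paeoniae Radix Alba (Baishao)	102	14.81
Aucklandiae Radix (Muxiang)	103	3.70
Notopterygii Rhizoma et Radix (Qianghuo)	104	3.70
Leonuri Herba (Yimucao)	105	59.26
Bupleuri Radix (Chaihu)	106	3.70
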
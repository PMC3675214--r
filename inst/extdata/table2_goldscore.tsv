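# scorer=goldscore polarity=higher
RGTFEGKF	49.12
RVTWEGKF	67.56
RGTFEGRF	65.36
RITFEIKF	63.48
RGTWEIKW	52.02
RGSWEGKF	52.86
RGSFEGKW	52.45
RGTWEVKF	59.31
RGSFEGKF	53.07
RVTWEVKF	52.27
RGTWEGKF	49.87
RGSWEGKW	49.26
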
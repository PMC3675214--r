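# scorer=chemscore polarity=lower
RGTFEGKF	-7.13
RVTWEGKF	-15.01
RGTFEGRF	-13.25
RITFEIKF	-10.86
RGTWEIKW	-10.39
RGSWEGKF	-10.11
RGSFEGKW	-10.04
RGTWEVKF	-9.35
RGSFEGKF	-8.95
RVTWEVKF	-8.83
RGTWEGKF	-8.83
RGSWEGKW	-8.20
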
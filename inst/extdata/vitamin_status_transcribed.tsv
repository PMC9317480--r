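pathway	step	gene	BaSm	SsSm	BaPl	SsPl
riboflavin	ribA	ribA	MISSING	INTACT	MISSING	INTACT
riboflavin	ribD	ribD	MISSING	INTACT	MISSING	INTACT
riboflavin	phosphatase	ybjI	MISSING	MISSING	MISSING	MISSING
riboflavin	phosphatase	yigB	MISSING	MISSING	MISSING	MISSING
riboflavin	phosphatase	yigL	MISSING	PSEUDOGENE	MISSING	INTACT
riboflavin	ribB	ribB	MISSING	INTACT	MISSING	INTACT
riboflavin	ribH	ribH	MISSING	INTACT	MISSING	INTACT
riboflavin	ribE	ribE	MISSING	INTACT	MISSING	INTACT
riboflavin	ribC	ribC	MISSING	INTACT	MISSING	INTACT
riboflavin	ribC	ribF	MISSING	MISSING	MISSING	MISSING
biotin	bioC	bioC	INTACT	MISSING	INTACT	MISSING
biotin	bioH	bioH	INTACT	MISSING	INTACT	MISSING
biotin	bioF	bioF	INTACT	MISSING	INTACT	MISSING
biotin	bioA	bioA	MISSING	INTACT	MISSING	PSEUDOGENE
biotin	bioD	bioD	MISSING	INTACT	MISSING	PSEUDOGENE
biotin	bioB	bioB	MISSING	INTACT	MISSING	INTACT
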
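line_id	complex	tissue	activity_pct
SYN01	CIII	fibroblast	12.1
SYN02	CI	fibroblast	23.7
SYN03	CI	fibroblast	7.9
SYN04	CIV	fibroblast	24
SYN05	CIV	fibroblast	5.2
SYN06	CI	fibroblast	20.3
SYN07	CIII	fibroblast	33.5
SYN08	CI	fibroblast	31.6
SYN09	CIII	fibroblast	96.7
SYN10	CIV	fibroblast	89.4
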
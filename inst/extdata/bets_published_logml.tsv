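segment	clock	estimator	logml_het	logml_iso	bf_printed
RdRp	SC	PS	176580.2855	176878.692	298.4064438
RdRp	SC	SS	176567.3726	176899.6801	332.3074985
RdRp	URLC	PS	175969.1107	176250.5675	281.4567672
RdRp	URLC	SS	175969.1107	176274.2038	305.0930831
capsid	SC	PS	405357.6929	405449.0548	91.36191103
capsid	SC	SS	405397.271	405479.4964	82.22538598
capsid	URLC	PS	405085.058	405842.493	757.4349536
capsid	URLC	SS	405116.8626	405877.5076	760.6449583
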
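roi	area	hemisphere	n_subrois	inferred
LSTC	STC	left	34	FALSE
RSTC	STC	right	29	FALSE
LMFG	MFG	left	43	FALSE
RMFG	MFG	right	50	FALSE
LIFG	IFG	left	23	FALSE
RIFG	IFG	right	14	FALSE
LPreC	PreC	left	30	TRUE
RPreC	PreC	right	30	TRUE
LSMG	SMG	left	34	FALSE
RSMG	SMG	right	32	FALSE
LAG	AG	left	33	FALSE
RAG	AG	right	37	FALSE
LSPL	SPL	left	76	FALSE
RSPL	SPL	right	80	FALSE
LOC	OC	left	62	FALSE
ROC	OC	right	51	FALSE
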
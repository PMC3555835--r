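library_id	breed	group	total_counts
IB	Iberian	EU	4022
WB	WildBoar	EU	18391
LD	Landrace	EA	13704
LW	LargeWhite	EA	23815
PT	Pietrain	EA	20215
ME	Meishan	AS	17407
VT	Vietnamese	AS	17751
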
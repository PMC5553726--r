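gene	variant	consequence	polyphen2	sift	mutation_taster	lrt
BBS2	p.(Arg189*)	stop_gained	not_applicable	not_applicable	Disease_causing	Deleterious
BBS2	p.(Tyr644*)	stop_gained	not_applicable	not_applicable	Disease_causing	Deleterious
ALMS1	p.(Arg2669*)	stop_gained	not_applicable	not_applicable	Disease_causing	Deleterious
CORO2B	p.(Leu194Gln)	missense_variant	Probably_damaging	Tolerated	Disease_causing	Deleterious
SLC3A1	p.(Tyr461His)	missense_variant	Probably_damaging	Tolerated	Disease_causing	Deleterious
LMO7	p.(Pro297Leu)	missense_variant	Probably_damaging	Damaging	Disease_causing	Deleterious
ZNF17	p.(Glu635*)	stop_gained	not_applicable	not_applicable	Disease_causing	Deleterious
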
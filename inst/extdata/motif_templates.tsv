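# Synthetic consensus templates for the domain detectors and the element
# generator.  These are editable stand-ins: replace with curated consensi to
# retune the detectors.  Columns: motif <TAB> amino-acid sequence.
# Linker-safe design: templates other than the zinc-finger parts avoid C and H
# so the zinc-finger grammar cannot fire inside them.
MYB	WTREEDEKLVSLVQKFGTRRWSLIAQQLPGRTDNAIKNFWNSTMRRK
RLE	GLKTEDLAVRSGWKEVANEVTRSTDGVSYLEFKLTNARGEVVSRSTASPELAEKL
KNUCKLE	CQKCGKEGHFAREC
RT0	FLGWQKTSGLPQGS
RT1	ISPLLFNLVMDELA
RT2	TRVRYVDDWLVLAE
RT3	EGLEINPTKTQVVA
RT4	FRPIKVGGQVVERV
RT5	QYADDVLLFAKSPE
RT6	NLGVELDSWGNEAR
RT7	AWMPVKRELFKRTV
ZNF_MID	KAFSRSDELTRM
ZNF_TAIL	IKRT
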
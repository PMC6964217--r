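# Ternary sponge-miRNA-mRNA associations curated for cardiovascular disease.
# Section marker lines name the sponge class; rows are sponge<TAB>miRNA<TAB>mRNA,
# with NA when no downstream mRNA was reported. Multi-gene cells are '/'-separated.
lncRNA
MIAT	miR-181b	STAT3
SNHG1	miR-195	BCL2L2
Kcnq1ot1	miR-214-3p	caspase-1
APPAT	miR-647	NA
MALAT1	miR-214	XBP1
XIST	miR-130a-3p	PDE4D
HOTAIR	miR-1	NA
UCA1	miR-1	BCL2/HSP60
RNCR3	miR-185-5p	KLF2
H19	miR-103	FADD
H19	miR-107	FADD
novlnc6	miR-133a	BMP10/Nxk2.5
novlnc6	miR-2499	BMP10/Nxk2.5
novlnc6	miR-30c	BMP10/Nxk2.5
circRNA
circRNA_007878	let-7e	NA
circDLGAP4	miR-143	HECTD1
circR-284	miR-221	NA
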
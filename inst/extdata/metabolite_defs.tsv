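# Default metabolite panel: formula and carbon-provenance slots.
# slots format: pool:n_positions entries separated by ';', '-' for none.
# Pools: one_carbon, methyl, glycine, trp_intracellular (intact block).
name	formula	slots
tryptophan	C11H12N2O2	trp_intracellular:11
kynurenine	C10H12N2O3	trp_intracellular:10
formate	CH2O2	one_carbon:1
serine	C3H7NO3	one_carbon:1;glycine:2
glycine	C2H5NO2	glycine:2
methionine	C5H11NO2S	methyl:1
AMP	C10H14N5O7P	one_carbon:2;glycine:2
ADP	C10H15N5O10P2	one_carbon:2;glycine:2
ATP	C10H16N5O13P3	one_carbon:2;glycine:2
GMP	C10H14N5O8P	one_carbon:2;glycine:2
GDP	C10H15N5O11P2	one_carbon:2;glycine:2
GTP	C10H16N5O14P3	one_carbon:2;glycine:2
acetyl-CoA	C23H38N7O17P3S	one_carbon:2
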
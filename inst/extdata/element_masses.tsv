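# Monoisotopic atomic masses (Da), IUPAC/CODATA values.
# version: 1
symbol	mass
C	12.0
H	1.00782503207
N	14.0030740048
O	15.9949146196
P	30.97376163
S	31.97207100
Na	22.9897692809
K	38.96370668
Li	7.01600455
Cl	34.96885268
F	18.99840322
Br	78.9183371
I	126.904473
Si	27.9769265325
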
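condition	n_lysosomes_per_cell	mean_area	mean_intensity
DMSO	38.4	0.92	118.5
CHQ	100.2	2.41	401.7
Clomp	83.6	3.03	462.3
Ethop	105.4	2.24	388.1
Pimo	118.9	2.05	344.9
ClompR	60.5	2.12	296.4
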
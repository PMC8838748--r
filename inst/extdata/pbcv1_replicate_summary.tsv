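population	treatment	n_polymorphic_endpoint	nucleotide_diversity
WD_1	weak_demography	34	1.115e-05
WD_2	weak_demography	44	1.537e-05
WD_3	weak_demography	38	0.717e-05
SD_1	strong_demography	54	0.334e-05
SD_2	strong_demography	56	0.662e-05
SD_3	strong_demography	52	0.705e-05
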
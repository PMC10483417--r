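kingdom	species_total	n_ge1	n_ge50
Archaea	12709	665	109
Bacteria	471432	14248	6128
Eukaryota	1420577	13698	456
Viruses	49675	672	0
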
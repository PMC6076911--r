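name	x	y	z
Superior & transverse temporal gyrus (R)	62	-18	23
Superior & transverse temporal gyrus (L)	-50	-15	11
Cuneus/Precuneus (19/31) (R)	9	-64	25
Cuneus/Precuneus (19/31) (L)	-15	-64	25
Middle occipital gyrus (L)	-45	-52	7
Precentral gyrus (L)	-33	-19	46
Superior frontal gyrus (R)	6	5	46
Prefrontal cortex (L)	3	47	16
Superior parietal cortex (R)	54	-22	52
Basal ganglia/NAc (R)	15	-1	-5
Isthmus of Cingulate Gyrus (L)	-9	-40	1
Thalamus (R)	9	-13	10
Thalamus (L)	-15	-19	-2
Brainstem (R)	6	-19	-23
Parahippocampal gyrus (L)	-21	-28	-27
Parahippocampal gyrus (R)	27	-25	-14
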
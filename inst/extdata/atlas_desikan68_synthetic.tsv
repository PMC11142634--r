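label	hemisphere	x	y	z	icn
lh-bankssts	L	-53	-47	10	dorsal-attention
lh-caudalanteriorcingulate	L	-5	20	28	ventral-attention
lh-caudalmiddlefrontal	L	-36	12	48	dorsal-attention
lh-cuneus	L	-7	-81	25	visual
lh-entorhinal	L	-24	-8	-32	limbic
lh-frontalpole	L	-9	62	-8	default-mode
lh-fusiform	L	-36	-50	-18	visual
lh-inferiorparietal	L	-43	-64	34	default-mode
lh-inferiortemporal	L	-50	-42	-22	default-mode
lh-insula	L	-36	-2	4	ventral-attention
lh-isthmuscingulate	L	-7	-45	26	default-mode
lh-lateraloccipital	L	-30	-87	6	visual
lh-lateralorbitofrontal	L	-25	32	-16	limbic
lh-lingual	L	-14	-70	-6	visual
lh-medialorbitofrontal	L	-7	38	-16	default-mode
lh-middletemporal	L	-56	-30	-10	default-mode
lh-paracentral	L	-8	-26	58	somato-motor
lh-parahippocampal	L	-26	-32	-20	limbic
lh-parsopercularis	L	-48	14	14	ventral-attention
lh-parsorbitalis	L	-44	38	-10	fronto-parietal
lh-parstriangularis	L	-46	30	8	fronto-parietal
lh-pericalcarine	L	-12	-80	8	visual
lh-postcentral	L	-42	-26	50	somato-motor
lh-posteriorcingulate	L	-6	-28	40	default-mode
lh-precentral	L	-40	-12	48	somato-motor
lh-precuneus	L	-8	-58	40	default-mode
lh-rostralanteriorcingulate	L	-6	34	10	default-mode
lh-rostralmiddlefrontal	L	-32	42	24	fronto-parietal
lh-superiorfrontal	L	-12	24	50	default-mode
lh-superiorparietal	L	-26	-58	56	dorsal-attention
lh-superiortemporal	L	-54	-16	2	somato-motor
lh-supramarginal	L	-52	-42	32	ventral-attention
lh-temporalpole	L	-32	12	-34	limbic
lh-transversetemporal	L	-44	-22	10	somato-motor
rh-bankssts	R	53	-47	10	dorsal-attention
rh-caudalanteriorcingulate	R	5	20	28	ventral-attention
rh-caudalmiddlefrontal	R	36	12	48	dorsal-attention
rh-cuneus	R	7	-81	25	visual
rh-entorhinal	R	24	-8	-32	limbic
rh-frontalpole	R	9	62	-8	default-mode
rh-fusiform	R	36	-50	-18	visual
rh-inferiorparietal	R	43	-64	34	default-mode
rh-inferiortemporal	R	50	-42	-22	default-mode
rh-insula	R	36	-2	4	ventral-attention
rh-isthmuscingulate	R	7	-45	26	default-mode
rh-lateraloccipital	R	30	-87	6	visual
rh-lateralorbitofrontal	R	25	32	-16	limbic
rh-lingual	R	14	-70	-6	visual
rh-medialorbitofrontal	R	7	38	-16	default-mode
rh-middletemporal	R	56	-30	-10	default-mode
rh-paracentral	R	8	-26	58	somato-motor
rh-parahippocampal	R	26	-32	-20	limbic
rh-parsopercularis	R	48	14	14	ventral-attention
rh-parsorbitalis	R	44	38	-10	fronto-parietal
rh-parstriangularis	R	46	30	8	fronto-parietal
rh-pericalcarine	R	12	-80	8	visual
rh-postcentral	R	42	-26	50	somato-motor
rh-posteriorcingulate	R	6	-28	40	default-mode
rh-precentral	R	40	-12	48	somato-motor
rh-precuneus	R	8	-58	40	default-mode
rh-rostralanteriorcingulate	R	6	34	10	default-mode
rh-rostralmiddlefrontal	R	32	42	24	fronto-parietal
rh-superiorfrontal	R	12	24	50	default-mode
rh-superiorparietal	R	26	-58	56	dorsal-attention
rh-superiortemporal	R	54	-16	2	somato-motor
rh-supramarginal	R	52	-42	32	ventral-attention
rh-temporalpole	R	32	12	-34	limbic
rh-transversetemporal	R	44	-22	10	somato-motor
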
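dopamine_receptors	synthetic example set	DRD1	DRD2	DRD3	DRD4	DRD5
gaba_receptors	synthetic example set	GABRA1	GABRA2	GABRB1	GABRB2	GABRG2	GABBR1
glutamate_ionotropic	synthetic example set	GRIA1	GRIA2	GRIN1	GRIN2A	GRIN2B	GRIK1	GRIK3
acetylcholine_receptors	synthetic example set	CHRNA3	CHRNA4	CHRNA7	CHRM1	CHRM4
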
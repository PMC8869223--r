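# Example genes-of-interest list: murine genes repeatedly implicated in
# NAFLD/NASH development or reported as dysregulated by maternal obesity.
# One gene per line; optional tab-separated source note.
Mttp	lipoprotein assembly
Pparg	PPAR signalling / adipogenesis
Slc2a2	hepatic glucose transport (GLUT2)
Srebf1	lipogenesis master regulator
Mertk	NASH fibrosis risk locus
Fgf21	hepatokine, glucose/lipid homeostasis
Fgfr1	FGF receptor
Tlr2	innate immune receptor
Ppara	fatty-acid oxidation
Ppard	PPAR family
Casp6	apoptosis effector
Vim	mesenchymal marker
Egfr	receptor tyrosine kinase
Vegfb	angiogenic factor
Wnt2	Wnt signalling
Wnt5b	Wnt signalling
Nrp1	VEGF co-receptor
Tle1	transcriptional repressor
Casp7	apoptosis executioner
Daam1	Wnt/planar cell polarity
Agtr1a	renin-angiotensin system
Lcn2	innate immune defence
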
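GO:0006915	apoptotic process
GO:0042981	regulation of apoptosis
GO:0007165	signal transduction
GO:0006355	regulation of transcription
GO:0016301	kinase activity
GO:0006468	protein phosphorylation
GO:0005634	nucleus
GO:0008283	cell proliferation
GO:0006954	inflammatory response
GO:0016032	viral process
GO:0006281	dna repair
GO:0007049	cell cycle
GO:0005615	extracellular space
GO:0045087	innate immune response
GO:0001525	angiogenesis
GO:0006412	translation
GO:0015031	protein transport
GO:0030154	cell differentiation
GO:0007155	cell adhesion
GO:0006629	lipid metabolic process
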
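# Mapping from tree metadata keys to ISA-Tab investigation-file fields.
# map	<key>	<ISA-Tab section>	<ISA-Tab field>
# assay	<assay type>	<measurement type>	<technology type>
map	Title	INVESTIGATION	Investigation Title
map	Description	INVESTIGATION	Investigation Description
map	Start date	INVESTIGATION	Investigation Submission Date
map	Principal investigator	INVESTIGATION CONTACTS	Investigation Person Last Name
map	Title	STUDY	Study Title
map	Description	STUDY	Study Description
map	Start date	STUDY	Study Submission Date
map	Experimental design	STUDY DESIGN DESCRIPTORS	Study Design Type
assay	RNAisol	transcription profiling	nucleic acid extraction
assay	qPCR	transcription profiling	quantitative PCR
assay	NGS	transcription profiling	nucleotide sequencing
assay	Statistics	data transformation	computational analysis
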
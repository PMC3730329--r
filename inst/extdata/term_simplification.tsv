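original_term	simplified_term
cell death	death
death	death
multicellular organismal development	development
embryonic development	development
anatomical structure morphogenesis	development
cell differentiation	differentiation
differentiation	differentiation
regulation of gene expression, epigenetic	epigenetics
cell growth	growth
growth	growth
cellular component organization	intracellular organization
organelle organization	intracellular organization
mitochondrion organization	intracellular organization
cytoplasm organization	intracellular organization
metabolic process	metabolism
cellular amino acid and derivative metabolic process	metabolism
secondary metabolic process	metabolism
lipid metabolic process	metabolism
biosynthetic process	metabolism
catabolic process	metabolism
carbohydrate metabolic process	metabolism
protein metabolic process	metabolism
nucleobase nucleoside nucleotide and nucleic acid metabolic process	metabolism
DNA metabolic process	metabolism
generation of precursor metabolites and energy	metabolism
signal transduction	signaling
response to biotic stimulus	signaling
response to external stimulus	signaling
response to abiotic stimulus	signaling
cell-cell signaling	signaling
cell communication	signaling
response to endogenous stimulus	signaling
cell recognition	signaling
protein transport	transport
transport	transport
regulation of biological process	NaN
biological process	NaN
behavior	NaN
protein modification process	protein modification
protein modification	protein modification
transcription	transcription
response to stress	stress
stress	stress
cell cycle	cell cycle
reproduction	reproduction
translation	translation
cytoskeleton organization	cytoskeleton
cytoskeleton	cytoskeleton
ion transport	ion transport
cell proliferation	proliferation
proliferation	proliferation
homeostatic process	homeostasis
homeostasis	homeostasis
epigenetics	epigenetics
development	development
intracellular organization	intracellular organization
metabolism	metabolism
signaling	signaling
NaN	NaN
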
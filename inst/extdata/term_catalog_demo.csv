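curie,label,ontology
NCIT:C25150,Age,ncit
NCIT:C28421,Sex,ncit
NCIT:C17357,Education,ncit
NCIT:C15220,Diagnosis,ncit
NCIT:C75186,Mini Mental State Examination,ncit
NCIT:C100137,Boston Naming Test,ncit
NCIT:C120981,Clinical Dementia Rating,ncit
NCIT:C94608,Amyloid Beta Peptide,ncit
NCIT:C105387,Tau Protein,ncit
NCIT:C102814,Apolipoprotein E,ncit
EFO:0005246,cerebrospinal fluid biomarker measurement,efo
EFO:0004352,body mass index,efo
HP:0002511,Alzheimer disease,hp
HP:0001268,Mental deterioration,hp
HP:0000726,Dementia,hp
SNOMED:86406008,Mini-mental state examination,snomed
SNOMED:273617000,Boston naming test,snomed
SNOMED:386807006,Memory impairment,snomed
LOINC:72106-8,Total score MMSE,loinc
LOINC:54637-4,ADAS-cog total score,loinc
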
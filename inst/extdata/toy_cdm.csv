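#meta {"name":"toy-cdm","version":"0.1.0","provenance":"hand-written toy catalog for examples and tests"}
"variable_id","label","definition","modality","data_type","range_kind","min","max","categories","ontology_refs"
"age","Age","Age of the subject at baseline, in years.","demographics","float","numeric",55,90,"","NCIT:C25150"
"sex","Sex","Biological sex of the subject.","demographics","categorical","enumeration",,,"M|F","NCIT:C28421"
"mmse_total","MMSE total score","Mini-Mental State Examination total score.","neuropsychology","integer","numeric",0,30,"","NCIT:C75186"
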
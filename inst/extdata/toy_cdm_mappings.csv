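"cdm_variable_id","study_id","source_label","method","score"
"age","ADNI","AGE","manual",
"sex","ADNI","PTGENDER","manual",
"mmse_total","ADNI","MMSE","manual",
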
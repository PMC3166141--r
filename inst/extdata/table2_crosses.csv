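family,maternal_id,paternal_id,maternal_genotype,paternal_genotype,n_pollinations,n_fruit,predicted,ambiguous
1-3,1-3:S1a+S3ab,1-3:S1a+S3ab,S1a+S3ab,S1a+S3ab,33,0,incompatible,FALSE
1-3,1-3:S1b+S3ab,1-3:S1b+S3ab,S1b+S3ab,S1b+S3ab,17,0,incompatible,FALSE
1-3,1-3:S1a+S3c,1-3:S1a+S3c,S1a+S3c,S1a+S3c,8,1,incompatible,FALSE
1-3,1-3:S1b,1-3:S1b,S1b,S1b,23,10,incompatible,TRUE
1-2,1-2:S1a+S2de,1-2:S1a+S2de,S1a+S2de,S1a+S2de,18,4,incompatible,FALSE
1-2,1-2:S1b+S2de,1-2:S1b+S2de,S1b+S2de,S1b+S2de,13,1,incompatible,FALSE
1-2,1-2:S1a+S1b,1-2:S1a+S1b,S1a+S1b,S1a+S1b,17,0,incompatible,FALSE
1-3,1-3:S1a+S3ab,1-3:S1a+S3c,S1a+S3ab,S1a+S3c,17,16,semi_compatible,FALSE
1-3,1-3:S1b+S3ab,1-3:S1b+S3c,S1b+S3ab,S1b+S3c,20,18,semi_compatible,FALSE
1-3,1-3:S1a+S3ab,1-3:S1b+S3ab,S1a+S3ab,S1b+S3ab,7,7,semi_compatible,FALSE
1-2,1-2:S1b+S2de,1-2:S1b+S2?,S1b+S2de,S1b+S2?,5,5,semi_compatible,FALSE
1-2,1-2:S1a+S2de,1-2:S1b+S2de,S1a+S2de,S1b+S2de,11,10,semi_compatible,FALSE
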
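family,maternal_id,paternal_id,maternal_genotype,paternal_genotype,n_pollinations,n_fruit,predicted,ambiguous
8-1,8-1:S8a+S1c,8-1:S8a+S1c,S8a+S1c,S8a+S1c,7,0,incompatible,FALSE
8-1,8-1:S8b+S1d,8-1:S8b+S1d,S8b+S1d,S8b+S1d,5,0,incompatible,FALSE
8-1,8-1:S8b+S1c,8-1:S8b+S1c,S8b+S1c,S8b+S1c,3,0,incompatible,FALSE
25-4,25-4:S25a+S4a,25-4:S25a+S4a,S25a+S4a,S25a+S4a,32,0,incompatible,FALSE
25-4,25-4:S25b+S4a,25-4:S25b+S4a,S25b+S4a,S25b+S4a,16,8,incompatible,FALSE
25-4,25-4:S25a+S4d,25-4:S25a+S4d,S25a+S4d,S25a+S4d,11,0,incompatible,FALSE
25-4,25-4:S25b+S4d,25-4:S25b+S4d,S25b+S4d,S25b+S4d,18,12,incompatible,FALSE
8-1,8-1:S8a+S1c,8-1:S8b+S1c,S8a+S1c,S8b+S1c,7,7,semi_compatible,FALSE
8-1,8-1:S8a+S1d,8-1:S8b+S1d,S8a+S1d,S8b+S1d,7,7,semi_compatible,FALSE
25-4,25-4:S4a+S25a,25-4:S4d+S25a,S4a+S25a,S4d+S25a,20,20,semi_compatible,FALSE
25-4,25-4:S4a+S25a,25-4:S4a+S25b,S4a+S25a,S4a+S25b,12,12,semi_compatible,FALSE
25-4,25-4:S4a+S25b,25-4:S4d+S25b,S4a+S25b,S4d+S25b,18,18,semi_compatible,FALSE
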
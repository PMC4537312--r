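text,ade_id,expected,family
"Patient did not have dystonia",dystonia,removed,negation_before
"She denied any dystonic reactions",dystonia,removed,negation_before
"Possibility of dystonia with ZZZZZ",dystonia,removed,negative_effects
"Dystonia Society have always been a useful resource for patients",dystonia,removed,organisation
"If Dystonia develops give procyclidine dose",dystonia,removed,hypothetical
"Check for any dystonic reaction",dystonia,removed,monitor
"His mother had developed dystonia many years ago",dystonia,removed,other_person
"her dystonia had become worse",dystonia,positive,retain_possessive
"his dystonia had become a problem",dystonia,positive,retain_possessive
"her dystonia was severe",dystonia,positive,retain_possessive
"his dystonia being reduced",dystonia,positive,retain_possessive
"The patient does not think the dystonia was painful",dystonia,positive,retain_override
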
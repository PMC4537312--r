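# third-person references: the ADE belongs to someone other than the patient
mother
father
brother
sister
husband
wife
son
daughter
aunt
uncle
cousin
grandmother
grandfather
nephew
niece
friend
neighbour
flatmate
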
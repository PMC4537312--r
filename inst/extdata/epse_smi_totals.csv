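ade_id,total_patients
dystonia,390
akathisia,750
parkinsonism,440
tardive_dyskinesia,324
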
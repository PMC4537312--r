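tardive dyskinesia
tardive dyskinesias
orofacial dyskinesia
oro facial dyskinesia
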
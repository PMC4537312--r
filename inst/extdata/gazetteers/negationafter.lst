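# negation cues occurring after the ADE term
ruled out
unlikely
excluded
absent
not present
not evident
was negative
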
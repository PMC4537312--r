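# negation cues occurring before the ADE term
not
no
never
denied
denies
denying
without
no evidence of
no sign of
no signs of
no history of
free of
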
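# cues linking the ADE term to a drug's listed effects
secondary to
induced by
attributable to
associated with
adverse effects of
drug induced
medication induced
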
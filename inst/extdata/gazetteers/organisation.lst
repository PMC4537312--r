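# charity / research organisation terms adjacent to an ADE name
society
association
workshop
trust
charity
foundation
support group
research group
network
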
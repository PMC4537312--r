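# clinicians monitoring for a potential ADE
check for
checking for
monitor for
monitoring for
observe for
observing for
watch for
watching for
look out for
screen for
screening for
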
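# warning / counselling about a potential or common side effect
side effect
side effects
risk of
risks of
can cause
may cause
could cause
warned about
warned of
warning of
possibility of
potential for
counselled about
advised about
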
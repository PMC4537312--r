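# diagnostic phrases giving strong evidence of a real ADE (retain stage);
# reconstructed seed list - extend for production use
diagnosed with
diagnosis of
suffering from
suffers from
treated for
treatment for
known to have
presents with
presented with
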
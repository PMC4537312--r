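akathisia
# curated alternate spellings seen in clinical records
acathisia
acasthisia
akithisia
akathesia
akathisic
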
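peak_id	transcript_id
a1	s1
a2	s2
a2	s3
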
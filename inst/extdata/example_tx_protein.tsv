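transcript_id	protein_id
s1	p
s2	p
s3	p
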
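chain_id	doc_id	member_text
c1	doc1	right lower extremity
c1	doc1	RLE
c2	doc1	peritoneal cavity
c2	doc1	PC
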
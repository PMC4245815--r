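AAAAAA
GAAAAA
AGAAAA
GGAAAA
AAGAAA
GAGAAA
AGGAAA
GGGAAA
AAAGAA
GAAGAA
AGAGAA
GGAGAA
AAGGAA
GAGGAA
AGGGAA
GGGGAA
AAAAGA
GAAAGA
AGAAGA
GGAAGA
AAGAGA
GAGAGA
AGGAGA
GGGAGA
AAAGGA
GAAGGA
AGAGGA
GGAGGA
AAGGGA
GAGGGA
AGGGGA
GGGGGA
AAAAAG
GAAAAG
AGAAAG
GGAAAG
AAGAAG
GAGAAG
AGGAAG
GGGAAG
AAAGAG
GAAGAG
AGAGAG
GGAGAG
AAGGAG
GAGGAG
AGGGAG
GGGGAG
AAAAGG
GAAAGG
AGAAGG
GGAAGG
AAGAGG
GAGAGG
AGGAGG
GGGAGG
AAAGGG
GAAGGG
AGAGGG
GGAGGG
AAGGGG
GAGGGG
AGGGGG
GGGGGG
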
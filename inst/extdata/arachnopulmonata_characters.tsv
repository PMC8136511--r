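tip	promenade	brood_care	book_lungs	wgd_arachnopulmonata
Xiphosura	0	0	0	0
Opiliones	0	0	0	0
Parasitiformes	0	0	0	0
Acariformes	0	0	0	0
Scorpiones	1	1	1	1
Pseudoscorpiones	1	1	0	1
Araneae	0	0	1	1
Amblypygi	1	1	1	1
Uropygi	1	1	1	1
Schizomida	1	1	1	1
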
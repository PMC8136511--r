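(Xiphosura,(Opiliones,(Parasitiformes,(Acariformes,((Scorpiones,Pseudoscorpiones),(Araneae,(Amblypygi,(Uropygi,Schizomida))))))));
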
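(outgroup_dac,(acariform_dac,((spider_dac1,(scorpion_dac1,pseudoscorpion_dac1)),(spider_dac2,(scorpion_dac2,pseudoscorpion_dac2)))));
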
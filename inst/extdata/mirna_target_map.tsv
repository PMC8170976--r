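mirna	protein
let-7i-5p	Nefl
miR-10a-5p	Nefl
miR-22-3p	Nefl
miR-23a-3p	Nefl
miR-30c-5p	Nefl
miR-99a-5p	Nefl
miR-125a-5p	Nefl
miR-126-3p	Nefl
miR-126-5p	Nefl
miR-181a-5p	Nefl
let-7i-5p	Vamp2
miR-10a-5p	Vamp2
miR-22-3p	Vamp2
miR-30c-5p	Vamp2
miR-99a-5p	Vamp2
miR-135a-5p	Vamp2
miR-338-3p	Vamp2
miR-350-3p	Vamp2
miR-377-3p	Vamp2
miR-495-3p	Vamp2
miR-17-5p	Calb2
miR-22-3p	Calb2
miR-30c-5p	Calb2
miR-495-3p	Calb2
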
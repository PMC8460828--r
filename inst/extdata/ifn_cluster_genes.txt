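IFNB1
IFNA1
IFNA2
IFNA8
IFNA13
IFNA21
IFNE
IFNW1
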
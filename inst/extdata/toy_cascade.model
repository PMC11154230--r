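# minimal linear cascade with one reversible step
species A 100 ligand
species B 10
species C 1 product
reaction r1: A <-> B kf1 kr1
reaction r2: B -> C k2
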
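# Literature reference: molecular properties relevant to descriptor computation.
# mw: molecular weight (g/mol); n_heavy: non-hydrogen atoms; n_bonds: total
# bonds including those to hydrogen; n_rings: ring count.
solute,formula,mw,n_heavy,n_bonds,n_rings
glucose,C6H12O6,180.18,12,24,1
fructose,C6H12O6,180.18,12,24,1
xylose,C5H10O5,150.15,10,20,1
sucrose,C12H22O11,342.34,23,46,2
sorbitol,C6H14O6,182.20,12,25,0
xylitol,C5H12O5,152.17,10,21,0
glycerol,C3H8O3,92.11,6,13,0
erythritol,C4H10O4,122.14,8,17,0
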
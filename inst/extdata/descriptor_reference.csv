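# Literature reference: information index on atomic composition (I_AC, bits),
# first Zagreb index (Z1) and global information index (G = I_AC + Z1),
# indices rounded to two decimals.
solute,I_AC,Z1,G
glucose,36.00,58,94.00
fructose,36.00,60,96.00
xylose,30.00,48,78.00
sucrose,67.95,120,187.95
sorbitol,37.89,50,87.89
xylitol,31.87,40,71.87
glycerol,19.79,20,39.79
erythritol,25.84,30,55.84
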
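# Literature reference: Norrish constants fitted to experimental water-activity
# data for binary aqueous solutions at ambient temperature.
# xs_min/xs_max: experimental solute mole-fraction range; phi_min: attained
# least-squares objective; epsilon: mean absolute error in a_w.
solute,xs_min,xs_max,k_N,phi_min,epsilon
glucose,0.023,0.111,-2.920,1.71e-5,1.00e-3
fructose,0.026,0.142,-2.351,6.76e-6,6.64e-4
xylose,0.020,0.059,-2.196,1.30e-6,2.71e-4
sucrose,0.018,0.098,-6.777,6.87e-6,5.85e-4
sorbitol,0.018,0.113,-2.494,4.18e-5,1.35e-3
xylitol,0.020,0.112,-2.221,1.12e-6,7.46e-4
glycerol,0.010,0.312,-0.908,1.65e-5,9.70e-4
erythritol,0.007,0.069,-0.950,4.28e-6,7.08e-4
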
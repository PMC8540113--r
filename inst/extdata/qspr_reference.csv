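# Literature reference: least-squares parameters of the five QSPR model forms
# for the Norrish constant, with sum of squared errors (theta) and variance
# statistic (phi = theta / (n - p), evaluated with the full solute count n = 8).
form,quantity,value
linear2,a11,1.333
linear2,a12,-8.39e-2
linear2,a13,-1.87e-2
linear2,theta,4.15e-1
linear2,phi,8.29e-2
power2,a21,-1.44e-2
power2,a22,1.026
power2,a23,3.81e-1
power2,theta,2.67e-1
power2,phi,5.35e-2
linearG,b11,8.90e-1
linearG,b12,-3.98e-2
linearG,theta,4.98e-1
linearG,phi,8.29e-2
powerG,b21,-7.65e-3
powerG,b22,1.295
powerG,theta,3.35e-1
powerG,phi,5.58e-2
polyG,b31,-2.18e-2
polyG,b32,-7.52e-5
polyG,theta,3.10e-1
polyG,phi,5.17e-2
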
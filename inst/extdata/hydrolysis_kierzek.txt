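# Measured non-enzymatic dinucleotide hydrolysis rates (per time unit)
# ordered dinucleotide (5'->3')   rate
UA 0.000953
CA 0.000932
UC 0.000846
CC 0.000846
UG 0.000100
CG 0.000100
UU 0.000100
CU 0.000100
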
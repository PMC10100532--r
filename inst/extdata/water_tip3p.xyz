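3
water with TIP3P partial charges in the 5th column (angstrom)
O   0.000000   0.000000   0.117300  -0.834
H   0.000000   0.757200  -0.469200   0.417
H   0.000000  -0.757200  -0.469200   0.417
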
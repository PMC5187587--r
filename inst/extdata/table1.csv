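residue,carbon,context,shift_ppm,uncertain
Xn,1,twofold-cell-wall,105.2,FALSE
Xn,2,twofold-cell-wall,72.3,FALSE
Xn,3,twofold-cell-wall,75.2,TRUE
Xn,4,twofold-cell-wall,82.2,FALSE
Xn,5,twofold-cell-wall,64.3,FALSE
Xn,1,threefold-cell-wall,102.6,FALSE
Xn,2,threefold-cell-wall,73.7,FALSE
Xn,3,threefold-cell-wall,74.7,FALSE
Xn,4,threefold-cell-wall,77.4,FALSE
Xn,5,threefold-cell-wall,63.9,FALSE
Xn,1,threefold-solution,102.5,FALSE
Xn,2,threefold-solution,73.5,FALSE
Xn,3,threefold-solution,74.4,FALSE
Xn,4,threefold-solution,77.2,FALSE
Xn,5,threefold-solution,63.7,FALSE
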
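residue,carbon,context,shift_ppm,uncertain,source
Glc,1,cellulose-domain-1,105.1,FALSE,observed
Glc,2,cellulose-domain-1,71.8,FALSE,synthetic
Glc,3,cellulose-domain-1,74.8,FALSE,synthetic
Glc,4,cellulose-domain-1,89.0,FALSE,observed
Glc,5,cellulose-domain-1,72.3,FALSE,synthetic
Glc,6,cellulose-domain-1,65.3,FALSE,observed
Glc,1,cellulose-domain-2,104.5,FALSE,synthetic
Glc,2,cellulose-domain-2,72.0,FALSE,synthetic
Glc,3,cellulose-domain-2,75.0,FALSE,synthetic
Glc,4,cellulose-domain-2,84.1,FALSE,observed
Glc,5,cellulose-domain-2,75.5,FALSE,synthetic
Glc,6,cellulose-domain-2,62.6,FALSE,observed
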
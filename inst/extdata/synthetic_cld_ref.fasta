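>synthetic_cld_ref
TYLITRQMTEKGKGTYILMSLIVKMDMADVSGLYMMSHLARVFAWDTLARTSWLIIRRTT
RVILDQDAVTPAWYYETRMYIMPDQGRKYR
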
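# Functional-site annotation in human eIF4E1a numbering. Cap-pocket
# residues: the Trp56/Trp102 cation-pi sandwich, Glu103 (H-bond to N2 of
# guanine), Trp166, the phosphate-chain binders Asp90/Arg112/Arg157/
# Lys162 and the C-terminal loop 204-211. The partner-site list (eIF4G /
# 4E-BP helix face) is illustrative and editable.
- class: cap_pocket
  residues:
    - {label: W56,  position: 56}
    - {label: D90,  position: 90}
    - {label: W102, position: 102}
    - {label: E103, position: 103}
    - {label: R112, position: 112}
    - {label: R157, position: 157}
    - {label: K162, position: 162}
    - {label: W166, position: 166}
    - {label: Cterm204, position: 204}
    - {label: Cterm205, position: 205}
    - {label: Cterm206, position: 206}
    - {label: Cterm207, position: 207}
    - {label: Cterm208, position: 208}
    - {label: Cterm209, position: 209}
    - {label: Cterm210, position: 210}
    - {label: Cterm211, position: 211}
- class: partner_site
  residues:
    - {label: V69,  position: 69}
    - {label: W73,  position: 73}
    - {label: L131, position: 131}
    - {label: E132, position: 132}
    - {label: D143, position: 143}
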
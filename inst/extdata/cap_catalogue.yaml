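# Cap-ligand catalogue: reference charges and ionization model per analogue.
#
# base_charge is the net charge with every listed group protonated (the
# low-pH limit of net_charge()); phosphate protons that are fully
# dissociated across the physiological range are folded into base_charge.
# For N7-alkylated guanine the +1 ring charge is included in base_charge.
#
# pKa values are ILLUSTRATIVE: literature-range values for the N1 proton
# of (7-alkyl)guanosine (pKa1) and for the secondary dissociation of the
# terminal phosphate (pKa2). Edit this file to use measured constants;
# net charges computed from the defaults are qualitative only.
- name: GTP
  base_charge: -3
  groups:
    - {label: "N1-H (guanine)", pKa: 9.4, delta: -1}
    - {label: "terminal phosphate (pKa2)", pKa: 6.5, delta: -1}
- name: m7GMP
  base_charge: 0
  groups:
    - {label: "N1-H (m7G)", pKa: 7.2, delta: -1}
    - {label: "terminal phosphate (pKa2)", pKa: 6.3, delta: -1}
- name: m7GDP
  base_charge: -1
  groups:
    - {label: "N1-H (m7G)", pKa: 7.2, delta: -1}
    - {label: "terminal phosphate (pKa2)", pKa: 6.4, delta: -1}
- name: m7GTP
  base_charge: -2
  groups:
    - {label: "N1-H (m7G)", pKa: 7.2, delta: -1}
    - {label: "terminal phosphate (pKa2)", pKa: 6.5, delta: -1}
- name: m7Gp4
  base_charge: -3
  groups:
    - {label: "N1-H (m7G)", pKa: 7.2, delta: -1}
    - {label: "terminal phosphate (pKa2)", pKa: 6.6, delta: -1}
- name: m7Gp5
  base_charge: -4
  groups:
    - {label: "N1-H (m7G)", pKa: 7.2, delta: -1}
    - {label: "terminal phosphate (pKa2)", pKa: 6.6, delta: -1}
- name: et7GTP
  base_charge: -2
  groups:
    - {label: "N1-H (et7G)", pKa: 7.3, delta: -1}
    - {label: "terminal phosphate (pKa2)", pKa: 6.5, delta: -1}
- name: bn7GDP
  base_charge: -1
  groups:
    - {label: "N1-H (bn7G)", pKa: 7.3, delta: -1}
    - {label: "terminal phosphate (pKa2)", pKa: 6.4, delta: -1}
- name: m227GTP
  base_charge: -2
  groups:
    - {label: "N1-H (m227G)", pKa: 7.5, delta: -1}
    - {label: "terminal phosphate (pKa2)", pKa: 6.5, delta: -1}
# Dinucleotides: the triphosphate bridge carries -3 when fully ionized
# (no free terminal secondary proton), +1 for the N7-methyl ring.
- name: m7GpppG
  base_charge: -2
  groups:
    - {label: "N1-H (m7G)", pKa: 7.2, delta: -1}
    - {label: "N1-H (second G)", pKa: 9.4, delta: -1}
- name: m7GpppA
  base_charge: -2
  groups:
    - {label: "N1-H (m7G)", pKa: 7.2, delta: -1}
- name: m7G2OpppG
  base_charge: -2
  groups:
    - {label: "N1-H (m7G)", pKa: 7.2, delta: -1}
    - {label: "N1-H (second G)", pKa: 9.4, delta: -1}
- name: m7Gpppm2OG
  base_charge: -2
  groups:
    - {label: "N1-H (m7G)", pKa: 7.2, delta: -1}
    - {label: "N1-H (second G)", pKa: 9.4, delta: -1}
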
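# SMARTS vocabulary used for descriptor-level substructure counting
# (matched by OpenBabel). The ester/ether definitions deliberately
# exclude the urethane (carbamate) motif so that polyester-/polyether-
# derived bonds are distinguished from the urethane linkages every
# fragment carries:
#   urethane  N-C(=O)-O-C
#   ester     C-C(=O)-O-C with the carbonyl carbon NOT bonded to N
#   ether     C-O-C with neither neighbour a carbonyl carbon
.pf_pat <- list(
  urethane  = "[NX3][CX3](=[OX1])[OX2][#6]",
  ester     = "[#6][CX3;!$([CX3][#7])](=[OX1])[OX2][#6]",
  ether     = "[#6;!$([CX3]=[OX1])][OX2][#6;!$([CX3]=[OX1])]",
  aromatic  = "[a]",
  benzenoid = "c1ccccc1",
  isocyanate = "[NX2]=[CX2]=[OX1]",
  # generic rotatable bond: non-ring single bond between two non-terminal
  # heavy atoms, neither in a triple bond ...
  rot_generic = "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]",
  # ... minus amide/carbamate C-N single bonds
  rot_amide   = "[NX3;!D1]-!@[CX3]=[OX1]"
)
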